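new_collider_fit <- function(beta, se, n_used, method) {
  fit <- tibble::tibble(
    beta = beta,
    se = se,
    z = beta / se,
    ci_low = beta - Z_CRIT * se,
    ci_high = beta + Z_CRIT * se,
    n_used = as.integer(n_used)
  )
  class(fit) <- c("collider_fit", class(fit))
  attr(fit, "method") <- method
  fit
}

#' Unadjusted regression of outcome on allele score
#'
#' Ordinary least squares of outcome on allele score with intercept --
#' deliberately *not* adjusting for the phenotype, which is what makes the
#' fit vulnerable to selection-induced collider bias. With
#' `selected_only = TRUE` (the default) the fit is restricted to selected
#' individuals (`s == 1`), i.e. the actual study sample.
#'
#' The coefficient and its classical OLS standard error are computed from
#' the centered sufficient statistics (numerically identical to `lm()`; the
#' test suite asserts agreement to 1e-10). The 95% interval is the Wald
#' interval `beta +/- 1.959964 se`.
#'
#' @param pop A population tibble with columns `g`, `o` (and `s` when
#'   `selected_only`).
#' @param selected_only Restrict the fit to selected individuals?
#' @return A one-row tibble of class `"collider_fit"` with columns `beta`,
#'   `se`, `z`, `ci_low`, `ci_high`, `n_used`.
#' @examples
#' pop <- tibble::tibble(g = c(0, 1, 2), o = c(1, 3, 5), s = 1L)
#' fit_outcome_on_score(pop, selected_only = FALSE) # exact line: beta 2, se 0
#' @export
fit_outcome_on_score <- function(pop, selected_only = TRUE) {
  g <- pop$g
  o <- pop$o
  if (selected_only) {
    if (!("s" %in% names(pop)) || anyNA(pop$s)) {
      abort("`selected_only = TRUE` requires a filled selection indicator `s`.",
            class = "collidersim_degenerate_error")
    }
    keep <- selected_indices(pop)
    g <- g[keep]
    o <- o[keep]
  }
  ols_fit(g, o, method = if (selected_only) "ols_selected" else "ols_full")
}

ols_fit <- function(g, o, method) {
  n <- length(g)
  if (n < 3L) {
    abort(sprintf("OLS fit needs at least 3 observations, got %d.", n),
          class = "collidersim_degenerate_error")
  }
  gc <- g - mean(g)
  oc <- o - mean(o)
  sxx <- sum(gc * gc)
  if (sxx == 0) {
    abort("Allele score has zero variance: singular design.",
          class = "collidersim_singular_error")
  }
  beta <- sum(gc * oc) / sxx
  resid <- oc - beta * gc
  se <- sqrt(sum(resid * resid) / (n - 2) / sxx)
  new_collider_fit(beta, se, n, method)
}

#' Does a fit's 95% confidence interval contain a value?
#'
#' Boundary equality counts as containing. Used to accumulate the
#' "number of 95% CIs containing zero / the true value" columns of the
#' replicate summaries.
#'
#' @param fit A `collider_fit` (or any data frame with `ci_low`, `ci_high`).
#' @param value Reference value (zero for null scenarios, `gamma * r`
#'   otherwise).
#' @return Logical.
#' @export
ci_contains <- function(fit, value) {
  fit$ci_low <= value & value <= fit$ci_high
}

#' Inverse-probability-weighted regression of outcome on allele score
#'
#' Weighted least squares among selected individuals with weights equal to
#' the inverse of the true selection probability
#' `expit(alpha + log(or_p) p + log(or_o) o)`. With the true selection model
#' this removes the collider bias of the unweighted selected-sample fit.
#' Standard errors are robust (HC0 sandwich), since the weighted residuals
#' are heteroscedastic by construction.
#'
#' @param pop A population tibble with `s` filled.
#' @param alpha Selection-model intercept (as used in [apply_selection()]).
#' @param or_p,or_o Selection odds ratios per SD of phenotype / outcome.
#' @return A one-row `collider_fit` tibble.
#' @export
ipw_fit <- function(pop, alpha, or_p, or_o) {
  if (anyNA(pop$s)) {
    abort("Selection has not been applied; run `apply_selection()` first.",
          class = "collidersim_degenerate_error")
  }
  keep <- selected_indices(pop)
  if (length(keep) < 3L) {
    abort("IPW fit needs at least 3 selected observations.",
          class = "collidersim_degenerate_error")
  }
  d <- data.frame(g = pop$g[keep], o = pop$o[keep])
  if (var(d$g) == 0) {
    abort("Allele score has zero variance: singular design.",
          class = "collidersim_singular_error")
  }
  pr <- plogis(alpha + log(or_p) * pop$p[keep] + log(or_o) * pop$o[keep])
  d$w <- 1 / pr
  fit <- lm(o ~ g, data = d, weights = w)
  V <- sandwich::vcovHC(fit, type = "HC0")
  new_collider_fit(coef(fit)[["g"]], sqrt(V["g", "g"]), nrow(d), "ipw")
}

#' @export
tidy.collider_fit <- function(x, ...) {
  tibble::tibble(
    term = "allele_score",
    estimate = x$beta,
    std.error = x$se,
    statistic = x$z,
    conf.low = x$ci_low,
    conf.high = x$ci_high
  )
}

#' @export
glance.collider_fit <- function(x, ...) {
  tibble::tibble(
    nobs = x$n_used,
    method = attr(x, "method") %||% NA_character_
  )
}

#' Write fit results to a tab-separated file
#'
#' One row per fit, columns `beta`, `se`, `z`, `ci_low`, `ci_high`, `n_used`.
#'
#' @param fits A `collider_fit` tibble (one or more rows bound together).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_fit_results <- function(fits, path) {
  write.table(fits[, c("beta", "se", "z", "ci_low", "ci_high", "n_used")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
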
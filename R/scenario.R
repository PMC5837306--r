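#' Run one simulation scenario across replicates
#'
#' For each replicate: simulate the intended population, calibrate and apply
#' the logistic selection mechanism, fit the unadjusted outcome-on-allele-
#' score regression in the selected sample, and record the coefficient, its
#' z-score and whether the 95% Wald interval contains the reference value
#' (zero for null scenarios, the true coefficient `gamma * r` otherwise).
#' Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [scenario_config()].
#' @param keep_fits If `TRUE`, the per-replicate fit table is attached as
#'   attribute `"fits"`.
#' @return A one-row tibble of class `"scenario_summary"` with the scenario
#'   settings and the across-replicate summaries `mean_beta`, `sd_beta`,
#'   `mean_z`, `sd_z`, `true_beta`, `reference_value`, `n_ci_covering`,
#'   `mean_n_selected`.
#' @examples
#' \donttest{
#' run_scenario(scenario_config(n_population = 2e5, r = 0.3, or_p = 1.8,
#'                              n_reps = 5, seed = 7))
#' }
#' @export
run_scenario <- function(cfg, keep_fits = FALSE) {
  cfg <- validate_scenario_config(cfg)
  alpha <- calibrate_intercept(cfg$or_p, cfg$or_o, cfg$gamma, cfg$target_fraction)
  reps <- cfg$n_reps
  beta <- se <- z <- numeric(reps)
  n_sel <- integer(reps)
  for (i in seq_len(reps)) {
    res <- tryCatch(
      {
        pop <- simulate_population(cfg, i - 1L)
        pop <- apply_selection(pop, alpha, cfg$or_p, cfg$or_o)
        fit_outcome_on_score(pop, selected_only = TRUE)
      },
      error = function(e) {
        abort(sprintf("Replicate %d failed: %s", i - 1L, conditionMessage(e)),
              class = "collidersim_replicate_error", parent = e)
      }
    )
    beta[i] <- res$beta
    se[i] <- res$se
    z[i] <- res$z
    n_sel[i] <- res$n_used
  }
  true_beta <- cfg$gamma * cfg$r
  reference <- if (cfg$gamma == 0) 0 else true_beta
  ci_low <- beta - Z_CRIT * se
  ci_high <- beta + Z_CRIT * se
  covering <- sum(ci_low <= reference & reference <= ci_high)
  out <- tibble::tibble(
    or_p = cfg$or_p,
    or_o = cfg$or_o,
    r = cfg$r,
    gamma = cfg$gamma,
    variance_explained = 100 * cfg$r^2,
    mean_beta = mean(beta),
    sd_beta = sd(beta),
    mean_z = mean(z),
    sd_z = sd(z),
    true_beta = true_beta,
    reference_value = reference,
    n_ci_covering = as.integer(covering),
    n_reps = reps,
    mean_n_selected = mean(n_sel),
    n_population = cfg$n_population,
    target_fraction = cfg$target_fraction,
    seed = cfg$seed,
    alpha = alpha
  )
  class(out) <- c("scenario_summary", class(out))
  if (keep_fits) {
    attr(out, "fits") <- tibble::tibble(
      replicate = seq_len(reps) - 1L, beta = beta, se = se, z = z,
      ci_low = ci_low, ci_high = ci_high, n_selected = n_sel,
      covers_reference = ci_low <= reference & reference <= ci_high
    )
  }
  out
}

#' Run a grid of scenarios (the replicate-summary tables)
#'
#' Crosses selection odds ratios with allele-score--phenotype correlations
#' and runs each cell with [run_scenario()]. Rows are ordered by descending
#' odds ratio, then ascending `r`, matching the layout of the published
#' grids (3 ORs x 5 correlations). Each cell gets a distinct deterministic
#' seed `base_cfg$seed + cell index`, so cells are independent and the whole
#' grid reproduces bit-for-bit from `base_cfg`.
#'
#' @param ors Selection odds ratios (applied to both phenotype and outcome).
#' @param rs Allele-score--phenotype correlations.
#' @param gamma Phenotype-on-outcome coefficient (0 for the null grid,
#'   0.1 for the non-null grid).
#' @param base_cfg Template [scenario_config()] supplying population size,
#'   target fraction, replicate count and base seed.
#' @return A tibble of class `"collider_grid"`, one row per scenario.
#' @export
run_grid <- function(ors = c(1.8, 1.5, 1.2),
                     rs = c(0.05, 0.10, 0.15, 0.20, 0.30),
                     gamma = 0,
                     base_cfg = scenario_config(gamma = gamma)) {
  if (length(ors) == 0 || length(rs) == 0) {
    abort("`ors` and `rs` must be non-empty.", class = "collidersim_config_error")
  }
  cells <- tidyr::expand_grid(
    or = sort(as.numeric(ors), decreasing = TRUE),
    r = sort(as.numeric(rs))
  )
  rows <- purrr::pmap(
    list(cells$or, cells$r, seq_len(nrow(cells))),
    function(or, r, k) {
      cfg <- scenario_config(
        n_population = base_cfg$n_population,
        r = r,
        gamma = gamma,
        or_p = or,
        or_o = or,
        target_fraction = base_cfg$target_fraction,
        n_reps = base_cfg$n_reps,
        seed = base_cfg$seed + k - 1L
      )
      run_scenario(cfg)
    }
  )
  out <- dplyr::bind_rows(rows)
  class(out) <- c("collider_grid", class(out))
  out
}

#' Write scenario summaries as a tab-separated table
#'
#' One row per scenario: `or`, `r`, `variance_explained` (percent), mean and
#' SD of the coefficient, mean and SD of the z-score, the true coefficient,
#' the CI coverage count and the replicate count, formatted to the precision
#' of the published grids (coefficients 4 decimals, z-scores 2).
#'
#' @param rows A `scenario_summary` / `collider_grid` tibble (>= 1 row).
#' @param destination Output file path.
#' @return `destination`, invisibly.
#' @export
write_summary_table <- function(rows, destination) {
  if (is.null(rows) || nrow(rows) == 0) {
    abort("`rows` must contain at least one scenario summary.",
          class = "collidersim_io_error")
  }
  formatted <- data.frame(
    or = sprintf("%.1f", rows$or_p),
    r = sprintf("%.2f", rows$r),
    variance_explained = sprintf("%.2f", rows$variance_explained),
    mean_beta = sprintf("%.4f", rows$mean_beta),
    sd_beta = sprintf("%.4f", rows$sd_beta),
    mean_z = sprintf("%.2f", rows$mean_z),
    sd_z = sprintf("%.2f", rows$sd_z),
    true_beta = sprintf("%.4f", rows$true_beta),
    n_ci_covering = rows$n_ci_covering,
    n_reps = rows$n_reps,
    check.names = FALSE
  )
  ok <- tryCatch(
    {
      write.table(formatted, destination, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      TRUE
    },
    error = function(e) {
      abort(sprintf("Cannot write summary table to '%s': %s",
                    destination, conditionMessage(e)),
            class = "collidersim_io_error")
    }
  )
  invisible(destination)
}

#' @export
glance.collider_grid <- function(x, ...) {
  tibble::tibble(
    n_scenarios = nrow(x),
    n_reps = x$n_reps[1],
    n_population = x$n_population[1],
    gamma = x$gamma[1]
  )
}

#' Plot bias across a scenario grid
#'
#' Mean selected-sample coefficient (with +/- 2 Monte Carlo SE ribbons)
#' against the allele-score--phenotype correlation, one line per selection
#' odds ratio. The dashed line marks the true population coefficient.
#'
#' @param object A `collider_grid` tibble from [run_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.collider_grid <- function(object, ...) {
  d <- dplyr::mutate(
    object,
    or = factor(.data$or_p),
    mc_se = .data$sd_beta / sqrt(.data$n_reps)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$mean_beta,
                                  colour = .data$or, group = .data$or)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_beta - 2 * .data$mc_se,
                                          ymax = .data$mean_beta + 2 * .data$mc_se)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$true_beta), linetype = "dashed",
                       colour = "grey40") +
    ggplot2::labs(
      x = "correlation between allele score and phenotype (r)",
      y = "mean selected-sample coefficient of outcome on allele score",
      colour = "selection OR per SD",
      title = "Collider bias induced by selective participation"
    ) +
    ggplot2::theme_minimal()
}
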
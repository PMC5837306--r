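# Intercept calibration for the logistic selection model.
#
# The selection linear predictor is alpha + sum_k b_k X_k where the X_k are
# jointly Gaussian with known covariance. The intercept alpha is chosen so
# the *expected* marginal selection probability equals the target fraction;
# the realized selected count is then binomial around the target ("controlled
# baseline risk of selection", approximately 500,000 of 9,000,000 at the
# defaults). The expectation is computed by tensor-product Gauss-Hermite
# quadrature over the joint Gaussian (Cholesky-transformed nodes), and alpha
# is found by root-finding; the logistic integrand is smooth, so 64 nodes per
# dimension reach far below the 1e-8 acceptance tolerance on the expectation.

# Expected selection fraction E[expit(alpha + b' X)], X ~ N(0, Sigma),
# at precomputed quadrature abscissae of the linear predictor.
gh_linear_predictor <- function(coefs, sigma, nodes = 64L) {
  m <- length(coefs)
  if (m == 0L) {
    return(list(eta = 0, w = 1))
  }
  if (m > 3L) {
    abort("Intercept calibration supports at most 3 selection covariates.",
          class = "collidersim_numerical_error")
  }
  gh <- pracma::gaussHermite(nodes)
  x <- sqrt(2) * gh$x
  w <- gh$w / sqrt(pi)
  L <- t(chol(sigma))
  grids <- vector("list", m)
  wgrids <- vector("list", m)
  for (j in seq_len(m)) {
    grids[[j]] <- x
    wgrids[[j]] <- w
  }
  Z <- as.matrix(expand.grid(grids))
  W <- Reduce(`*`, lapply(seq_len(m), function(j) expand.grid(wgrids)[[j]]))
  X <- Z %*% t(L)
  eta <- as.numeric(X %*% coefs)
  list(eta = eta, w = W)
}

calibrate_logistic_intercept <- function(coefs, sigma, target_fraction,
                                         nodes = 64L, tol = 1e-8) {
  if (target_fraction <= 0 || target_fraction >= 1) {
    abort("`target_fraction` must lie in (0, 1).", class = "collidersim_config_error")
  }
  q <- gh_linear_predictor(coefs, sigma, nodes)
  expectation <- function(alpha) sum(q$w * plogis(alpha + q$eta))
  span <- 10 * sum(abs(coefs)) + 1
  lo <- qlogis(target_fraction) - span
  hi <- qlogis(target_fraction) + span
  root <- tryCatch(
    uniroot(function(a) expectation(a) - target_fraction, c(lo, hi), tol = 1e-12),
    error = function(e) {
      abort(
        sprintf(
          "Intercept calibration failed to converge (target %.6g, coefs %s): %s",
          target_fraction, paste(signif(coefs, 4), collapse = ", "),
          conditionMessage(e)
        ),
        class = "collidersim_numerical_error"
      )
    }
  )
  alpha <- root$root
  achieved <- expectation(alpha)
  if (abs(achieved - target_fraction) > tol) {
    abort(
      sprintf(
        "Intercept calibration inaccurate: |E - target| = %.3g (alpha = %.6f).",
        abs(achieved - target_fraction), alpha
      ),
      class = "collidersim_numerical_error"
    )
  }
  alpha
}

#' Calibrate the selection-model intercept to a target selected fraction
#'
#' Finds the log-odds intercept `alpha` such that the expected marginal
#' probability of selection, `E[expit(alpha + log(or_p) P + log(or_o) O)]`,
#' equals `target_fraction`, where phenotype `P` and outcome `O` are
#' unit-variance bivariate Gaussian with correlation `gamma` (the structural
#' coefficient of phenotype on outcome, which is also their correlation when
#' both marginals have SD 1).
#'
#' The expectation is evaluated by two-dimensional Gauss-Hermite quadrature
#' and `alpha` found by root-finding to an absolute tolerance of `1e-8` on
#' the expectation.
#'
#' @param or_p,or_o Selection odds ratios per 1 SD of phenotype / outcome.
#' @param gamma Structural phenotype-on-outcome coefficient (and hence the
#'   correlation of `P` and `O`).
#' @param target_fraction Desired marginal selection probability.
#' @param nodes Gauss-Hermite nodes per dimension.
#' @return The log-odds intercept (a single number).
#' @examples
#' # with no covariate effects the intercept is just the logit of the target
#' calibrate_intercept(1, 1, 0, 1 / 18)
#' log(1 / 17)
#' @export
calibrate_intercept <- function(or_p, or_o, gamma = 0,
                                target_fraction = 500000 / 9000000,
                                nodes = 64L) {
  if (or_p <= 0 || or_o <= 0) {
    abort("Odds ratios must be positive.", class = "collidersim_config_error")
  }
  if (abs(gamma) >= 1) {
    abort("`gamma` must lie in (-1, 1).", class = "collidersim_config_error")
  }
  sigma <- matrix(c(1, gamma, gamma, 1), 2, 2)
  calibrate_logistic_intercept(c(log(or_p), log(or_o)), sigma,
                               target_fraction, nodes = nodes)
}
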
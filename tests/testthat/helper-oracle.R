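# Monte Carlo oracle for the selection-intercept calibration: draw a large
# sample of (phenotype, outcome) pairs from the bivariate Normal implied by
# gamma and bisect on alpha until the empirical mean selection probability
# hits the target. Independent of the Gauss-Hermite route it checks.
mc_alpha_oracle <- function(or_p, or_o, gamma, target_fraction,
                            n_draws = 1e7, tol = 1e-4, seed = 20240101) {
  withr::with_seed(seed, {
    p <- rnorm(n_draws)
    o <- gamma * p + sqrt(1 - gamma^2) * rnorm(n_draws)
  })
  eta <- log(or_p) * p + log(or_o) * o
  emp <- function(alpha) mean(plogis(alpha + eta))
  lo <- qlogis(target_fraction) - 10
  hi <- qlogis(target_fraction) + 10
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (emp(mid) < target_fraction) lo <- mid else hi <- mid
  }
  alpha <- (lo + hi) / 2
  stopifnot(abs(emp(alpha) - target_fraction) < tol)
  alpha
}

# small convenience: a quick reduced-scale scenario config
small_cfg <- function(n = 2e5, r = 0.3, gamma = 0, or = 1.5, reps = 5, seed = 1,
                      target = 500000 / 9000000) {
  scenario_config(n_population = n, r = r, gamma = gamma, or_p = or,
                  target_fraction = target, n_reps = reps, seed = seed)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
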
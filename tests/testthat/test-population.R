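# Monte Carlo tolerance: 4 standard errors of the statistic at the given n.
se_sd <- function(n) 1 / sqrt(2 * n)              # SE of a unit-Normal sample SD
se_cor <- function(r, n) (1 - r^2) / sqrt(n)      # SE of a sample correlation

test_that("population marginals, correlation and true slope match the structural model", {
  n <- 2e5
  cases <- list(
    list(r = 0, gamma = 0),
    list(r = 0.30, gamma = 0),
    list(r = 0.05, gamma = 0.1),
    list(r = 0.30, gamma = 0.1)
  )
  for (cs in cases) {
    cfg <- scenario_config(n_population = n, r = cs$r, gamma = cs$gamma,
                           n_reps = 1, seed = 404)
    pop <- simulate_population(cfg, 0)
    expect_equal(nrow(pop), n)
    expect_true(all(is.na(pop$s)))
    for (v in c("g", "p", "o")) {
      expect_lt(abs(sd(pop[[v]]) - 1), 4 * se_sd(n))
    }
    expect_lt(abs(cor(pop$g, pop$p) - cs$r), 4 * se_cor(cs$r, n))
    # population regression of outcome on allele score has slope gamma * r
    fit <- fit_outcome_on_score(pop, selected_only = FALSE)
    expect_lt(abs(fit$beta - cs$gamma * cs$r), 4 * fit$se)
  }
})

test_that("replicates are deterministic, distinct, and leave the caller's RNG alone", {
  cfg <- small_cfg(n = 1e4, reps = 3, seed = 77)
  set.seed(123)
  before <- runif(3)
  set.seed(123)
  a <- simulate_population(cfg, 1)
  b <- simulate_population(cfg, 1)
  other <- simulate_population(cfg, 2)
  after <- runif(3)
  expect_identical(a$g, b$g)
  expect_identical(a$p, b$p)
  expect_false(identical(a$g, other$g))
  expect_identical(before, after) # caller's stream position untouched
})

test_that("simulate_population validates the replicate index", {
  cfg <- small_cfg(n = 1e3, reps = 2)
  expect_error(simulate_population(cfg, 2), class = "collidersim_config_error")
  expect_error(simulate_population(cfg, -1), class = "collidersim_config_error")
})

test_that("selection hits the target fraction across the study's odds-ratio grid", {
  n <- 1e6
  f <- 500000 / 9000000
  tol <- 4 * sqrt(f * (1 - f) / n)
  for (or in c(1.2, 1.5, 1.8)) {
    for (gamma in c(0, 0.1)) {
      cfg <- scenario_config(n_population = n, r = 0.3, gamma = gamma,
                             or_p = or, n_reps = 1, seed = 500 + round(10 * or))
      alpha <- calibrate_intercept(or, or, gamma, f)
      pop <- apply_selection(simulate_population(cfg, 0), alpha, or, or)
      expect_lt(abs(mean(pop$s) - f), tol)
    }
  }
})

test_that("participation shifts phenotype means by ~0.2/0.4/0.6 SD for OR 1.2/1.5/1.8", {
  n <- 2e6
  expected <- c("1.2" = 0.2, "1.5" = 0.4, "1.8" = 0.6)
  for (or in c(1.2, 1.5, 1.8)) {
    cfg <- scenario_config(n_population = n, r = 0.3, gamma = 0, or_p = or,
                           n_reps = 1, seed = 600 + round(10 * or))
    alpha <- calibrate_intercept(or, or, 0, cfg$target_fraction)
    pop <- apply_selection(simulate_population(cfg, 0), alpha, or, or)
    shift <- participation_mean_shift(pop)
    expect_equal(round(shift$shift_p, 1), unname(expected[as.character(or)]))
    expect_equal(round(shift$shift_o, 1), unname(expected[as.character(or)]))
  }
})

test_that("neutral selection (OR = 1) is independent of phenotype and outcome", {
  cfg <- small_cfg(n = 5e5, or = 1, reps = 1, seed = 9, target = 0.25)
  alpha <- calibrate_intercept(1, 1, 0, 0.25)
  pop <- apply_selection(simulate_population(cfg, 0), alpha, 1, 1)
  shift <- participation_mean_shift(pop)
  n1 <- sum(pop$s)
  se_shift <- sqrt(1 / n1 + 1 / (nrow(pop) - n1))
  expect_lt(abs(shift$shift_p), 4 * se_shift)
  expect_lt(abs(shift$shift_o), 4 * se_shift)
  expect_equal(alpha, qlogis(0.25))
})

test_that("selection draws are reproducible and degenerate classes error", {
  cfg <- small_cfg(n = 1e4, reps = 2, seed = 12)
  pop <- simulate_population(cfg, 1)
  a <- apply_selection(pop, -2, 1.5, 1.5)
  b <- apply_selection(pop, -2, 1.5, 1.5)
  expect_identical(a$s, b$s)
  expect_error(participation_mean_shift(pop), class = "collidersim_degenerate_error")
  all_in <- pop
  all_in$s <- 1L
  expect_error(participation_mean_shift(all_in), class = "collidersim_degenerate_error")
})

test_that("populations can be dumped to a headered TSV", {
  cfg <- small_cfg(n = 50, reps = 1, seed = 3, target = 0.5)
  pop <- apply_selection(simulate_population(cfg, 0), 0, 1.5, 1.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_population(pop, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_identical(names(back), c("g", "p", "o", "s"))
  expect_equal(back$g, pop$g, tolerance = 1e-12)
  expect_identical(as.integer(back$s), pop$s)
})
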
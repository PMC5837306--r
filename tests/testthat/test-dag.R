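test_that("the coin toy enumerates to zero and exactly -1/2", {
  toy <- coin_toy()
  expect_equal(toy$correlation[toy$condition == "unconditional"], 0)
  expect_identical(toy$correlation[toy$condition == "conditional_on_bell"], -0.5)
  expect_equal(toy$n_outcomes, c(4L, 3L))
})

test_that("dag_spec validates structure", {
  expect_error(
    dag_spec(c("A", "B"), data.frame(from = c("A", "B"), to = c("B", "A"),
                                     weight = c(0.5, 0.5))),
    class = "collidersim_dag_error"
  )
  expect_error(dag_spec(c("G", "S")), class = "collidersim_dag_error")
  expect_error(
    dag_spec("G", data.frame(from = "G", to = "X", weight = 1)),
    class = "collidersim_dag_error"
  )
  expect_error(
    dag_spec(c("G", "P"), selection = data.frame(node = "P", or = 0)),
    class = "collidersim_dag_error"
  )
  # two strong correlated parents -> parental variance over 1, no unit scaling
  expect_error(
    dag_spec(c("A", "B", "C"),
             data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"),
                        weight = c(0.9, 0.9, 0.9))),
    class = "collidersim_dag_error"
  )
  expect_error(dag_preset("panelZ"), class = "collidersim_dag_error")
})

test_that("simulated nodes have unit SDs and the analytic covariance", {
  spec <- dag_preset("panelE")
  n <- 1e5
  d <- simulate_dag(spec, n, seed = 88)
  for (v in spec$nodes) {
    expect_lt(abs(sd(d[[v]]) - 1), 4 / sqrt(2 * n))
  }
  emp <- cor(as.matrix(d[spec$nodes]))
  expect_lt(max(abs(emp - spec$sigma)), 4 / sqrt(n) + 1e-3)
})

test_that("a single-node spec is standard Normal and selection-free specs hit the target", {
  d1 <- simulate_dag(dag_spec("G"), 5e4, seed = 3)
  expect_lt(abs(sd(d1$G) - 1), 4 / sqrt(2 * 5e4))
  spec <- dag_spec(c("G", "O"), target_fraction = 0.25)
  d2 <- simulate_dag(spec, 5e4, seed = 4)
  expect_lt(abs(mean(d2$s) - 0.25), 4 * sqrt(0.25 * 0.75 / 5e4))
  # selection independent of nodes: selected and unselected means agree
  expect_lt(abs(mean(d2$G[d2$s == 1]) - mean(d2$G[d2$s == 0])), 4 * sqrt(2 / (5e4 / 4)))
})

test_that("the core preset reproduces the population simulator draw for draw", {
  cfg <- scenario_config(n_population = 1e5, r = 0.3, gamma = 0.1,
                         or_p = 1.5, n_reps = 3, seed = 7)
  alpha <- calibrate_intercept(1.5, 1.5, 0.1, cfg$target_fraction)
  pop <- apply_selection(simulate_population(cfg, 1), alpha, 1.5, 1.5)
  spec <- dag_preset("core", r = 0.3, gamma = 0.1, or = 1.5,
                     target_fraction = cfg$target_fraction)
  d <- simulate_dag(spec, 1e5, seed = 7, replicate_index = 1)
  expect_identical(pop$g, d$G)
  expect_identical(pop$p, d$P)
  expect_identical(pop$o, d$O)
  expect_identical(pop$s, d$s)
  expect_identical(alpha, attr(d, "alpha"))
})

test_that("selection on phenotype only leaves the score-outcome null intact", {
  # no outcome involvement and no shared factor: no collider path to open
  spec <- dag_spec(c("G", "P", "O"),
                   data.frame(from = "G", to = "P", weight = 0.3),
                   data.frame(node = "P", or = 1.8),
                   target_fraction = 0.3)
  br <- bias_report(spec, n = 5e5, reps = 10, seed = 15)
  go <- br[br$association == "G_O", ]
  expect_equal(go$classification, "negligible")
  expect_lt(abs(go$bias), 3 * go$mc_se)
})

test_that("panel presets reproduce their qualitative selection-bias claims", {
  n <- 1e6
  reps <- 20
  report <- function(p) bias_report(dag_preset(p), n = n, reps = reps, seed = 5)
  cls <- function(br, assoc) br$classification[br$association == assoc]

  # spurious association induced where no causal path exists
  brA <- report("panelA")
  expect_equal(cls(brA, "G_O"), "negative")
  brB <- report("panelB")
  expect_false(cls(brB, "G_O") == "negligible")
  # causal effects biased by selection
  for (p in c("panelC", "panelD", "panelE")) {
    expect_false(cls(report(p), "G_O") == "negligible")
  }
  # phenotype-outcome biased, score-outcome clean
  brF <- report("panelF")
  expect_equal(cls(brF, "G_O"), "negligible")
  expect_false(cls(brF, "P_O") == "negligible")
  expect_s3_class(autoplot(brF), "ggplot")
})

test_that("dag specs round-trip through the plain-text format", {
  spec <- dag_preset("panelB")
  path <- withr::local_tempfile(fileext = ".dag")
  write_dag_spec(spec, path)
  back <- read_dag_spec(path)
  expect_identical(back$nodes, spec$nodes)
  expect_equal(back$edges, spec$edges)
  expect_equal(back$selection, spec$selection)
  expect_identical(back$sigma, spec$sigma)
  expect_error(read_dag_spec(tempfile()), class = "collidersim_io_error")
  writeLines("frobnicate G", path)
  expect_error(read_dag_spec(path), class = "collidersim_io_error")
})

test_that("bias_report requires the score and outcome nodes", {
  expect_error(bias_report(dag_spec(c("G", "P")), 100, 2, 1),
               class = "collidersim_dag_error")
})
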
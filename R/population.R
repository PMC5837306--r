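#' Simulate the intended study population
#'
#' Draws `n_population` individuals from the linear-Gaussian structural
#' model: allele score `G ~ N(0, 1)`; phenotype
#' `P = r G + sqrt(1 - r^2) e_P`; outcome
#' `O = gamma P + sqrt(1 - gamma^2) e_O`, with independent standard-Normal
#' noise. All three variables have unit marginal SD, `cor(G, P) = r`, and the
#' population regression coefficient of outcome on allele score is
#' `gamma * r`.
#'
#' Replicates are reproducible in isolation: replicate `i` uses the `i`-th
#' L'Ecuyer-CMRG stream derived from `cfg$seed` (see [apply_selection()] for
#' the selection substream). The caller's RNG state is left untouched.
#'
#' @param cfg A [scenario_config()].
#' @param replicate_index Zero-based replicate number in `[0, n_reps)`.
#' @return A tibble with one row per individual and columns `g`, `p`, `o`
#'   and `s` (selection indicator, `NA` until [apply_selection()] is run).
#'   The config and replicate index travel along as attributes.
#' @examples
#' pop <- simulate_population(scenario_config(n_population = 1e4, r = 0.3), 0)
#' sd(pop$g); cor(pop$g, pop$p)
#' @export
simulate_population <- function(cfg, replicate_index = 0L) {
  cfg <- validate_scenario_config(cfg)
  if (replicate_index < 0 || replicate_index >= cfg$n_reps) {
    abort(sprintf("`replicate_index` must lie in [0, %d).", cfg$n_reps),
          class = "collidersim_config_error")
  }
  n <- as.integer(cfg$n_population)
  state <- replicate_stream(cfg$seed, replicate_index, "population")
  cols <- with_rng_state(state, dag_sim_kernel(
    n,
    parents = list(integer(0), 0L, 1L),
    weights = list(numeric(0), cfg$r, cfg$gamma),
    noise_sd = c(1, sqrt(1 - cfg$r^2), sqrt(1 - cfg$gamma^2))
  ))
  pop <- tibble::tibble(
    g = cols[[1]],
    p = cols[[2]],
    o = cols[[3]],
    s = NA_integer_
  )
  attr(pop, "cfg") <- cfg
  attr(pop, "replicate_index") <- as.integer(replicate_index)
  pop
}

#' Apply the logistic selection mechanism
#'
#' Fills the selection indicator `s` with independent Bernoulli draws with
#' per-individual probability
#' `expit(alpha + log(or_p) * p + log(or_o) * o)` -- phenotype and outcome
#' act additively (no interaction) on the log-odds of participation. Draws
#' come from a dedicated selection substream of the replicate's RNG stream,
#' so selection is reproducible given `(seed, replicate_index)` and
#' independent of the population draws.
#'
#' @param pop A population tibble from [simulate_population()].
#' @param alpha Log-odds intercept, normally from [calibrate_intercept()].
#' @param or_p,or_o Selection odds ratios per SD of phenotype / outcome.
#' @param replicate_index,seed Identify the RNG substream; default to the
#'   values carried by `pop`.
#' @return `pop` with `s` filled (integer 0/1).
#' @export
apply_selection <- function(pop, alpha, or_p, or_o,
                            replicate_index = attr(pop, "replicate_index"),
                            seed = attr(pop, "cfg")$seed) {
  if (is.null(replicate_index) || is.null(seed)) {
    abort("`replicate_index` and `seed` must be supplied when `pop` does not carry them.",
          class = "collidersim_config_error")
  }
  if (or_p <= 0 || or_o <= 0) {
    abort("Odds ratios must be positive.", class = "collidersim_config_error")
  }
  n <- nrow(pop)
  state <- replicate_stream(seed, replicate_index, "selection")
  res <- with_rng_state(state, selection_kernel(
    list(pop$p, pop$o), c(log(or_p), log(or_o)), alpha, n
  ))
  pop$s <- res$s
  attr(pop, "selected_idx") <- res$idx
  attr(pop, "alpha") <- alpha
  pop
}

#' Mean phenotype and outcome shift between participants and non-participants
#'
#' The difference `mean(x | s = 1) - mean(x | s = 0)` for phenotype and
#' outcome, in SD units. Under selection odds ratios of 1.2, 1.5 and 1.8 per
#' SD (on both phenotype and outcome) the phenotype shift is about 0.2, 0.4
#' and 0.6 SD.
#'
#' @param pop A population tibble with `s` filled.
#' @return A one-row tibble with columns `shift_p` and `shift_o`.
#' @export
participation_mean_shift <- function(pop) {
  if (anyNA(pop$s)) {
    abort("Selection has not been applied; run `apply_selection()` first.",
          class = "collidersim_degenerate_error")
  }
  idx <- selected_indices(pop)
  n1 <- length(idx)
  n0 <- nrow(pop) - n1
  if (n1 == 0L || n0 == 0L) {
    abort("Both selection classes must be non-empty to compute mean shifts.",
          class = "collidersim_degenerate_error")
  }
  mean_by_class <- function(x) {
    s1 <- sum(x[idx])
    c(s1 / n1, (sum(x) - s1) / n0)
  }
  mp <- mean_by_class(pop$p)
  mo <- mean_by_class(pop$o)
  tibble::tibble(shift_p = mp[1] - mp[2], shift_o = mo[1] - mo[2])
}

# Selected-row indices: reuse the index vector collected by the selection
# kernel when present, otherwise scan `s`.
selected_indices <- function(pop) {
  idx <- attr(pop, "selected_idx")
  if (is.null(idx) || length(idx) != sum(pop$s == 1L)) {
    idx <- which(pop$s == 1L)
  }
  idx
}

#' Dump a (reduced-size) population to a tab-separated file
#'
#' Debugging aid: writes the per-individual columns `g`, `p`, `o`, `s` as a
#' headered TSV. Intended for populations far below the default nine million
#' rows.
#'
#' @param pop A population tibble.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path) {
  write.table(pop[, c("g", "p", "o", "s")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
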
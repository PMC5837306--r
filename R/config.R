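#' Configuration for one selection-bias simulation scenario
#'
#' Bundles every knob of a single scenario: the size of the intended study
#' population, the allele-score--phenotype correlation, the causal effect of
#' phenotype on outcome, the per-SD selection odds ratios, the marginal
#' selection fraction, the replicate count and the master seed.
#'
#' The defaults are the headline study conditions: an intended population of
#' nine million individuals of whom a fraction 1/18 (about 500,000) is
#' selected, and 100 replicates per scenario.
#'
#' @param n_population Number of individuals in the intended study population.
#' @param r Correlation between allele score and phenotype, in `[0, 1)`.
#' @param gamma Causal regression coefficient of phenotype on outcome
#'   (0 for null scenarios, 0.1 for the non-null grids). Must lie in
#'   `(-1, 1)` so the outcome noise variance `1 - gamma^2` stays positive.
#' @param or_p Odds ratio of selection per 1 SD increase in phenotype.
#' @param or_o Odds ratio of selection per 1 SD increase in outcome
#'   (defaults to `or_p`: equal, additively independent effects).
#' @param target_fraction Intended marginal selection probability.
#' @param n_reps Number of simulation replicates.
#' @param seed Master random seed (integer).
#'
#' @return A list of class `"scenario_config"`.
#' @examples
#' cfg <- scenario_config(n_population = 1e5, r = 0.3, or_p = 1.8, n_reps = 5)
#' cfg
#' @export
scenario_config <- function(n_population = 9e6,
                            r = 0.3,
                            gamma = 0,
                            or_p = 1.5,
                            or_o = or_p,
                            target_fraction = 500000 / 9000000,
                            n_reps = 100,
                            seed = 1L) {
  cfg <- structure(
    list(
      n_population = as.numeric(n_population),
      r = as.numeric(r),
      gamma = as.numeric(gamma),
      or_p = as.numeric(or_p),
      or_o = as.numeric(or_o),
      target_fraction = as.numeric(target_fraction),
      n_reps = as.integer(n_reps),
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
  validate_scenario_config(cfg)
}

validate_scenario_config <- function(cfg) {
  if (!inherits(cfg, "scenario_config")) {
    abort("`cfg` must be a scenario_config object.",
          class = "collidersim_config_error")
  }
  bad <- function(msg) abort(msg, class = "collidersim_config_error")
  with(cfg, {
    if (is.na(n_population) || n_population < 2) bad("`n_population` must be at least 2.")
    if (is.na(r) || r < 0 || r >= 1) bad("`r` must lie in [0, 1).")
    if (is.na(gamma) || abs(gamma) >= 1) {
      bad("`gamma` must lie in (-1, 1): the outcome noise variance 1 - gamma^2 must be positive.")
    }
    if (is.na(or_p) || or_p <= 0) bad("`or_p` must be positive.")
    if (is.na(or_o) || or_o <= 0) bad("`or_o` must be positive.")
    if (is.na(target_fraction) || target_fraction <= 0 || target_fraction >= 1) {
      bad("`target_fraction` must lie in (0, 1).")
    }
    if (is.na(n_reps) || n_reps < 1) bad("`n_reps` must be at least 1.")
    if (is.na(seed)) bad("`seed` must be an integer.")
  })
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config>\n")
  cat(sprintf("  intended population: %s, target selected fraction %.6f\n",
              format(x$n_population, big.mark = ","), x$target_fraction))
  cat(sprintf("  corr(allele score, phenotype) r = %.3f; phenotype -> outcome gamma = %.3f\n",
              x$r, x$gamma))
  cat(sprintf("  selection OR per SD: phenotype %.2f, outcome %.2f\n", x$or_p, x$or_o))
  cat(sprintf("  replicates: %d, seed: %d\n", x$n_reps, x$seed))
  invisible(x)
}

#' Read and write scenario configurations as flat key-value text
#'
#' The file format is one `key = value` pair per line, keys exactly matching
#' the [scenario_config()] fields (`n_population`, `r`, `gamma`, `or_p`,
#' `or_o`, `target_fraction`, `n_reps`, `seed`). Lines starting with `#` and
#' blank lines are ignored. Round-trips are lossless.
#'
#' @param cfg A `scenario_config`.
#' @param path File to read from / write to.
#' @return `read_scenario_config()` returns a `scenario_config`;
#'   `write_scenario_config()` returns `path` invisibly.
#' @export
write_scenario_config <- function(cfg, path) {
  cfg <- validate_scenario_config(cfg)
  lines <- vapply(
    names(unclass(cfg)),
    function(k) sprintf("%s = %s", k, format(cfg[[k]], digits = 17, scientific = FALSE)),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path), class = "collidersim_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    abort(sprintf("Malformed config line: '%s'", lines[bad][1]),
          class = "collidersim_io_error")
  }
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, character(1), 2L)))
  known <- c("n_population", "r", "gamma", "or_p", "or_o",
             "target_fraction", "n_reps", "seed")
  unknown <- setdiff(keys, known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "collidersim_io_error")
  }
  args <- as.list(vals)
  names(args) <- keys
  do.call(scenario_config, args)
}
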
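# Reproducibility contract: one master seed per scenario; replicate i draws
# from the i-th L'Ecuyer-CMRG stream derived from that seed, and within a
# replicate the population stage and the selection stage use distinct
# substreams. Any single replicate can therefore be regenerated in isolation,
# and the caller's RNG state is never disturbed.

rng_snapshot <- function() {
  get0(".Random.seed", envir = globalenv(), inherits = FALSE)
}

rng_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# Derive the CMRG stream state for (seed, replicate_index, stage).
replicate_stream <- function(seed, replicate_index, stage = c("population", "selection")) {
  stage <- match.arg(stage)
  if (!is.numeric(replicate_index) || length(replicate_index) != 1L ||
      is.na(replicate_index) || replicate_index < 0 ||
      replicate_index != floor(replicate_index)) {
    abort("`replicate_index` must be a single non-negative integer.",
          class = "collidersim_config_error")
  }
  old <- rng_snapshot()
  on.exit(rng_restore(old), add = TRUE)
  suppressWarnings(
    set.seed(as.integer(seed), kind = "L'Ecuyer-CMRG", normal.kind = "Inversion")
  )
  s <- get(".Random.seed", envir = globalenv())
  for (i in seq_len(replicate_index)) {
    s <- parallel::nextRNGStream(s)
  }
  if (stage == "selection") {
    s <- parallel::nextRNGSubStream(s)
  }
  s
}

# Evaluate `code` with .Random.seed set to `state`, restoring the caller's
# RNG state afterwards.
with_rng_state <- function(state, code) {
  old <- rng_snapshot()
  on.exit(rng_restore(old), add = TRUE)
  assign(".Random.seed", state, envir = globalenv())
  force(code)
}
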
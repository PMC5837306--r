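#' Define a small linear-Gaussian selection DAG
#'
#' A structural-equation graph over continuous nodes (typically a subset of
#' `G` = allele score, `P` = phenotype, `O` = outcome, `U` = shared
#' unobserved factor) plus an implicit binary selection node `S`. Each
#' continuous node is a weighted sum of its parents plus Gaussian noise
#' scaled so its marginal SD is exactly 1. Selection is a logistic function
#' of the nodes listed in `selection` (odds ratio per SD each), with the
#' intercept calibrated so the expected selected fraction equals
#' `target_fraction`.
#'
#' The constructor validates acyclicity, reorders nodes topologically, and
#' precomputes the analytic node covariance and per-node noise SDs; it
#' errors if some node's parental variance already exceeds 1 (no unit-SD
#' scaling exists).
#'
#' @param nodes Character vector of continuous node names (no `"S"`).
#' @param edges Data frame with columns `from`, `to`, `weight`; targets must
#'   be continuous nodes (selection is specified separately).
#' @param selection Data frame with columns `node`, `or`: the selection
#'   parents and their per-SD odds ratios. `NULL` or zero rows means
#'   selection is independent of every node.
#' @param target_fraction Expected marginal selected fraction.
#' @return A list of class `"dag_spec"`.
#' @examples
#' spec <- dag_spec(
#'   nodes = c("G", "P", "O"),
#'   edges = data.frame(from = "G", to = "P", weight = 0.3),
#'   selection = data.frame(node = c("P", "O"), or = c(1.5, 1.5))
#' )
#' spec
#' @export
dag_spec <- function(nodes, edges = NULL,
                     selection = NULL,
                     target_fraction = 500000 / 9000000) {
  bad <- function(msg) abort(msg, class = "collidersim_dag_error")
  nodes <- as.character(nodes)
  if (length(nodes) == 0 || anyDuplicated(nodes)) bad("`nodes` must be non-empty and unique.")
  if ("S" %in% nodes) bad("The selection node `S` is implicit; do not list it in `nodes`.")
  if (is.null(edges)) {
    edges <- data.frame(from = character(0), to = character(0), weight = numeric(0))
  }
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) > 0) {
    if (!all(c("from", "to", "weight") %in% names(edges))) {
      bad("`edges` needs columns from, to, weight.")
    }
    if (!all(edges$from %in% nodes)) bad("Edge sources must be listed nodes.")
    if (!all(edges$to %in% nodes)) {
      bad("Edge targets must be continuous nodes; selection parents go in `selection`.")
    }
    if (any(edges$from == edges$to)) bad("Self-loops are not allowed.")
    if (any(!is.finite(edges$weight))) bad("Edge weights must be finite.")
  }
  if (is.null(selection)) {
    selection <- data.frame(node = character(0), or = numeric(0))
  }
  selection <- tibble::as_tibble(selection)
  if (nrow(selection) > 0) {
    if (!all(c("node", "or") %in% names(selection))) {
      bad("`selection` needs columns node, or.")
    }
    if (!all(selection$node %in% nodes)) bad("Selection parents must be listed nodes.")
    if (anyDuplicated(selection$node)) bad("Duplicate selection parents.")
    if (any(!is.finite(selection$or) | selection$or <= 0)) {
      bad("Selection odds ratios must be positive and finite.")
    }
  }
  if (target_fraction <= 0 || target_fraction >= 1) {
    bad("`target_fraction` must lie in (0, 1).")
  }

  order <- topo_sort(nodes, edges)
  k <- length(order)
  idx <- stats::setNames(seq_len(k), order)
  parents <- vector("list", k)
  weights <- vector("list", k)
  noise_sd <- numeric(k)
  sigma <- matrix(0, k, k, dimnames = list(order, order))
  for (j in seq_len(k)) {
    e <- edges[edges$to == order[j], , drop = FALSE]
    pa <- idx[e$from]
    w <- e$weight
    parents[[j]] <- as.integer(pa - 1L)
    weights[[j]] <- as.numeric(w)
    var_lin <- if (length(pa) == 0) 0 else {
      as.numeric(t(w) %*% sigma[pa, pa, drop = FALSE] %*% w)
    }
    if (var_lin > 1 + 1e-12) {
      bad(sprintf(
        "Node %s: parental variance %.4f exceeds 1; no unit-SD noise scaling exists.",
        order[j], var_lin))
    }
    noise_sd[j] <- sqrt(max(0, 1 - var_lin))
    sigma[j, j] <- 1
    if (j > 1) {
      for (m in seq_len(j - 1)) {
        cv <- if (length(pa) == 0) 0 else sum(w * sigma[pa, m])
        sigma[j, m] <- sigma[m, j] <- cv
      }
    }
  }
  structure(
    list(
      nodes = order,
      edges = edges,
      selection = selection,
      target_fraction = as.numeric(target_fraction),
      parents = parents,
      weights = weights,
      noise_sd = noise_sd,
      sigma = sigma
    ),
    class = "dag_spec"
  )
}

topo_sort <- function(nodes, edges) {
  remaining <- nodes
  out <- character(0)
  dep <- split(edges$from, edges$to)
  while (length(remaining) > 0) {
    ready <- remaining[vapply(remaining, function(v) {
      length(setdiff(dep[[v]], out)) == 0
    }, logical(1))]
    # keep the user's node order among simultaneously ready nodes
    if (length(ready) == 0) {
      abort("The edge set contains a cycle.", class = "collidersim_dag_error")
    }
    out <- c(out, ready[1])
    remaining <- setdiff(remaining, ready[1])
  }
  out
}

#' @export
print.dag_spec <- function(x, ...) {
  cat("<dag_spec>\n")
  cat("  nodes (topological):", paste(x$nodes, collapse = ", "), "\n")
  if (nrow(x$edges) > 0) {
    cat("  edges:\n")
    for (i in seq_len(nrow(x$edges))) {
      cat(sprintf("    %s -> %s  (weight %.3f)\n",
                  x$edges$from[i], x$edges$to[i], x$edges$weight[i]))
    }
  } else cat("  edges: none\n")
  if (nrow(x$selection) > 0) {
    cat("  selection parents:\n")
    for (i in seq_len(nrow(x$selection))) {
      cat(sprintf("    %s -> S  (OR %.2f per SD)\n",
                  x$selection$node[i], x$selection$or[i]))
    }
  } else cat("  selection: independent of all nodes\n")
  cat(sprintf("  target selected fraction: %.6f\n", x$target_fraction))
  invisible(x)
}

#' Named selection-bias DAG presets
#'
#' `"core"` is the main simulation structure (`G -> P`, optional `P -> O`,
#' selection on both `P` and `O`); given the same parameters and seed it
#' reproduces [simulate_population()] + [apply_selection()] draw for draw.
#' The panel presets are minimal linear-Gaussian graphs exhibiting the
#' qualitative selection-bias behaviours of the classic scenario panels;
#' the exact topologies are:
#'
#' * `panelA`: `G -> P`; selection on `P` and `O`. No causal `G`--`O` path,
#'   but selection on the collider induces a (negative) `G`--`O` association.
#' * `panelB`: `G -> P`, `U -> P`, `U -> O`; selection on `P` only.
#'   Conditioning on a descendant of the collider `P` links `G` with `U`,
#'   so the non-causal `G`--`O` association becomes non-zero.
#' * `panelC`: `G -> P -> O`; selection on `P` and `O`. The causal `G`--`O`
#'   effect is biased (attenuated at these defaults).
#' * `panelD`: `G -> P -> O`; selection on `P` only. The causal effect is
#'   again biased.
#' * `panelE`: `G -> P -> O`, `U -> P`, `U -> O`; selection on `P` and `O`.
#' * `panelF`: `G -> P`, `U -> P`; selection on `O` and `U`. Selection opens
#'   `O`--`U` and hence biases the `P`--`O` association, while `G` stays
#'   d-separated from `O`: the `G`--`O` association is unbiased.
#'
#' The `core` preset defaults to the headline study conditions (selected
#' fraction 1/18 of the intended population). The panel presets are
#' qualitative demonstrations, and default to a 30% selected fraction --
#' realistic for attrition from a cohort -- and a shared-factor weight of
#' 0.5; with the study's tiny 1/18 participation fraction the selected
#' samples are so small that the panels' qualitative signatures drown in
#' Monte Carlo noise at demonstration-sized simulations.
#'
#' @param name One of `"core"`, `"panelA"` ... `"panelF"`.
#' @param r Allele-score--phenotype edge weight (correlation) for `G -> P`.
#' @param gamma Phenotype-on-outcome weight for presets with a `P -> O`
#'   edge; defaults to 0 for `core`/`panelA` and `weight` for the causal
#'   panels.
#' @param or Selection odds ratio per SD applied to every selection parent.
#' @param weight Weight for the remaining structural edges (`U -> P`,
#'   `U -> O`, `P -> O` in the causal panels).
#' @param target_fraction Expected selected fraction; defaults to 1/18 for
#'   `core` and 0.3 for the panels.
#' @return A [dag_spec()].
#' @export
dag_preset <- function(name, r = 0.3, gamma = NULL, or = 1.5, weight = 0.5,
                       target_fraction = NULL) {
  target_fraction <- target_fraction %||%
    if (identical(name, "core")) 500000 / 9000000 else 0.3
  e <- function(from, to, w) data.frame(from = from, to = to, weight = w)
  sel <- function(node) data.frame(node = node, or = or)
  specs <- list(
    core = function() {
      g <- gamma %||% 0
      edges <- e("G", "P", r)
      if (g != 0) edges <- rbind(edges, e("P", "O", g))
      dag_spec(c("G", "P", "O"), edges, sel(c("P", "O")), target_fraction)
    },
    panelA = function() {
      dag_spec(c("G", "P", "O"), e("G", "P", r), sel(c("P", "O")), target_fraction)
    },
    panelB = function() {
      dag_spec(c("G", "U", "P", "O"),
               rbind(e("G", "P", r), e("U", "P", weight), e("U", "O", weight)),
               sel("P"), target_fraction)
    },
    panelC = function() {
      g <- gamma %||% weight
      dag_spec(c("G", "P", "O"),
               rbind(e("G", "P", r), e("P", "O", g)),
               sel(c("P", "O")), target_fraction)
    },
    panelD = function() {
      g <- gamma %||% weight
      dag_spec(c("G", "P", "O"),
               rbind(e("G", "P", r), e("P", "O", g)),
               sel("P"), target_fraction)
    },
    panelE = function() {
      g <- gamma %||% weight
      dag_spec(c("G", "U", "P", "O"),
               rbind(e("G", "P", r), e("U", "P", weight),
                     e("P", "O", g), e("U", "O", weight)),
               sel(c("P", "O")), target_fraction)
    },
    panelF = function() {
      dag_spec(c("G", "U", "P", "O"),
               rbind(e("G", "P", r), e("U", "P", weight)),
               sel(c("O", "U")), target_fraction)
    }
  )
  builder <- specs[[name]]
  if (is.null(builder)) {
    abort(sprintf("Unknown preset '%s'. Available: %s.",
                  name, paste(names(specs), collapse = ", ")),
          class = "collidersim_dag_error")
  }
  builder()
}

#' Simulate data from a selection DAG
#'
#' Topological-order simulation of the continuous nodes (each a weighted sum
#' of parents plus Normal noise rescaled to unit marginal SD), followed by
#' logistic selection with the intercept calibrated so the expected selected
#' fraction equals `spec$target_fraction`. Uses the same per-replicate RNG
#' substream contract as [simulate_population()], so the `core` preset and
#' the population simulator produce identical draws for identical seeds.
#'
#' @param spec A [dag_spec()].
#' @param n Number of individuals.
#' @param seed Master seed.
#' @param replicate_index Zero-based replicate number.
#' @return A tibble with one column per node plus the selection indicator
#'   `s`.
#' @export
simulate_dag <- function(spec, n, seed, replicate_index = 0L) {
  if (!inherits(spec, "dag_spec")) {
    abort("`spec` must be a dag_spec.", class = "collidersim_dag_error")
  }
  n <- as.integer(n)
  state <- replicate_stream(seed, replicate_index, "population")
  cols <- with_rng_state(state, dag_sim_kernel(
    n, spec$parents, spec$weights, spec$noise_sd
  ))
  names(cols) <- spec$nodes
  out <- tibble::as_tibble(cols)

  selp <- spec$selection
  sel_state <- replicate_stream(seed, replicate_index, "selection")
  if (nrow(selp) == 0) {
    alpha <- qlogis(spec$target_fraction)
    res <- with_rng_state(sel_state, selection_kernel(list(), numeric(0), alpha, n))
  } else {
    coefs <- log(selp$or)
    sigma_sel <- spec$sigma[selp$node, selp$node, drop = FALSE]
    alpha <- calibrate_logistic_intercept(coefs, sigma_sel, spec$target_fraction)
    res <- with_rng_state(
      sel_state,
      selection_kernel(lapply(selp$node, function(v) out[[v]]), coefs, alpha, n)
    )
  }
  out$s <- res$s
  attr(out, "selected_idx") <- res$idx
  attr(out, "alpha") <- alpha
  attr(out, "spec") <- spec
  out
}

#' Bias of selected-sample associations implied by a DAG
#'
#' For the allele-score--outcome (`G`--`O`) and phenotype--outcome (`P`--`O`)
#' regressions, simulates `reps` replicates of size `n`, fits each
#' association in the full population and in the selected sample, and
#' reports the mean coefficients, the mean selection-induced difference
#' (bias), its Monte Carlo standard error, and a three-way classification:
#' `"negligible"` when `|bias| < 3 MC SE`, otherwise the bias sign.
#'
#' @param spec A [dag_spec()] containing nodes `G` and `O`.
#' @param n Individuals per replicate.
#' @param reps Number of replicates.
#' @param seed Master seed.
#' @return A tibble with one row per association.
#' @export
bias_report <- function(spec, n, reps = 20L, seed = 1L) {
  if (!all(c("G", "O") %in% spec$nodes)) {
    abort("`spec` must contain nodes G and O.", class = "collidersim_dag_error")
  }
  assocs <- list(c("G", "O"))
  if ("P" %in% spec$nodes) assocs <- c(assocs, list(c("P", "O")))
  diffs <- full <- selected <- matrix(NA_real_, nrow = reps, ncol = length(assocs))
  for (i in seq_len(reps)) {
    d <- simulate_dag(spec, n, seed, replicate_index = i - 1L)
    keep <- selected_indices(d)
    for (a in seq_along(assocs)) {
      x <- d[[assocs[[a]][1]]]
      y <- d[[assocs[[a]][2]]]
      bf <- ols_fit(x, y, "ols_full")$beta
      bs <- ols_fit(x[keep], y[keep], "ols_selected")$beta
      full[i, a] <- bf
      selected[i, a] <- bs
      diffs[i, a] <- bs - bf
    }
  }
  bias <- colMeans(diffs)
  mc_se <- apply(diffs, 2, sd) / sqrt(reps)
  out <- tibble::tibble(
    association = vapply(assocs, paste, character(1), collapse = "_"),
    mean_full = colMeans(full),
    mean_selected = colMeans(selected),
    bias = bias,
    mc_se = mc_se,
    classification = dplyr::case_when(
      abs(bias) < 3 * mc_se ~ "negligible",
      bias > 0 ~ "positive",
      TRUE ~ "negative"
    ),
    n = as.numeric(n),
    reps = as.integer(reps)
  )
  class(out) <- c("collider_bias_report", class(out))
  out
}

#' @export
autoplot.collider_bias_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$association, y = .data$bias,
                                       fill = .data$classification)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$bias - 3 * .data$mc_se,
                                        ymax = .data$bias + 3 * .data$mc_se),
                           width = 0.2) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = NULL, y = "selection-induced bias (selected - full coefficient)",
      title = "Selection-induced bias by association"
    ) +
    ggplot2::theme_minimal()
}

#' The two-coins-and-a-bell collider toy, by exact enumeration
#'
#' Two fair coins are tossed independently; a bell rings whenever either
#' shows heads. Enumerating the four equally likely outcomes shows the coins
#' are uncorrelated unconditionally, but conditional on hearing the bell
#' (outcomes HH, HT, TH, each with probability 1/3) the correlation is
#' exactly -1/2: conditioning on the collider induces a spurious inverse
#' association.
#'
#' @return A tibble with rows `"unconditional"` and `"conditional_on_bell"`
#'   and columns `correlation` and `n_outcomes`.
#' @examples
#' coin_toy()
#' @export
coin_toy <- function() {
  outcomes <- tidyr::expand_grid(coin1 = c(0L, 1L), coin2 = c(0L, 1L))
  outcomes$bell <- as.integer(outcomes$coin1 == 1L | outcomes$coin2 == 1L)
  exact_cor <- function(x, y) {
    # integer-arithmetic correlation over equally likely outcomes: exact in
    # doubles (all intermediate sums are small integers)
    n <- length(x)
    num <- n * sum(x * y) - sum(x) * sum(y)
    den <- sqrt((n * sum(x * x) - sum(x)^2) * (n * sum(y * y) - sum(y)^2))
    num / den
  }
  rang <- outcomes[outcomes$bell == 1L, ]
  tibble::tibble(
    condition = c("unconditional", "conditional_on_bell"),
    correlation = c(
      exact_cor(outcomes$coin1, outcomes$coin2),
      exact_cor(rang$coin1, rang$coin2)
    ),
    n_outcomes = c(nrow(outcomes), nrow(rang))
  )
}

#' Read and write DAG specifications as plain text
#'
#' A flat format: a `nodes` line, one `edge from to weight` line per edge,
#' one `select node or` line per selection parent, and a `target_fraction`
#' line. Round-trips through [dag_spec()] (which re-derives the covariance
#' and noise scales).
#'
#' @param spec A [dag_spec()].
#' @param path File to write to / read from.
#' @return `write_dag_spec()` returns `path` invisibly; `read_dag_spec()`
#'   returns a `dag_spec`.
#' @export
write_dag_spec <- function(spec, path) {
  lines <- c(
    paste("nodes", paste(spec$nodes, collapse = " ")),
    if (nrow(spec$edges) > 0) {
      sprintf("edge %s %s %s", spec$edges$from, spec$edges$to,
              format(spec$edges$weight, digits = 17))
    },
    if (nrow(spec$selection) > 0) {
      sprintf("select %s %s", spec$selection$node,
              format(spec$selection$or, digits = 17))
    },
    sprintf("target_fraction %s", format(spec$target_fraction, digits = 17))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dag_spec
#' @export
read_dag_spec <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("DAG spec file not found: %s", path),
          class = "collidersim_io_error")
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[[:space:]]+")
  nodes <- NULL
  edges <- list()
  selection <- list()
  target <- 500000 / 9000000
  for (tk in toks) {
    switch(tk[1],
      nodes = { nodes <- tk[-1] },
      edge = {
        edges[[length(edges) + 1L]] <-
          data.frame(from = tk[2], to = tk[3], weight = as.numeric(tk[4]))
      },
      select = {
        selection[[length(selection) + 1L]] <-
          data.frame(node = tk[2], or = as.numeric(tk[3]))
      },
      target_fraction = { target <- as.numeric(tk[2]) },
      abort(sprintf("Unknown DAG spec directive '%s'.", tk[1]),
            class = "collidersim_io_error")
    )
  }
  dag_spec(
    nodes,
    if (length(edges) > 0) do.call(rbind, edges) else NULL,
    if (length(selection) > 0) do.call(rbind, selection) else NULL,
    target
  )
}
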
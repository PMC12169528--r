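# Independent-cascade intervention simulator. Spread of a cascade with one
# activation attempt per edge is distributionally identical to reachability
# in a bond-percolated graph (each edge kept independently with its
# transmission probability), so runs are simulated by drawing per-run edge
# retention masks and computing reachable sets from the surviving seeds.
# Drawing the masks once per configuration gives exact common random
# numbers across intervention arms.

#' Cascade configuration
#'
#' @param seed_nodes non-empty character vector of misinformation
#'   originators, all present in the network the cascade runs on.
#' @param p per-edge transmission probability in `[0, 1]` (uniform; in
#'   weighted mode the edge probability is `min(1, p * weight)`).
#' @param runs Monte-Carlo replicates (>= 1).
#' @param seed integer RNG seed; the simulation is deterministic given
#'   `(network, config)`.
#' @param weighted scale the transmission probability by edge weight.
#' @return a `cascade_config`.
#' @export
cascade_config <- function(seed_nodes, p = 0.1, runs = 1000L, seed = 7L,
                           weighted = FALSE) {
  seed_nodes <- clean_id(as.character(seed_nodes))
  if (!length(seed_nodes)) stop_misinfluence("seed_nodes must be non-empty")
  if (!is.numeric(p) || p < 0 || p > 1) stop_misinfluence("p must lie in [0, 1]")
  if (runs < 1L) stop_misinfluence("runs must be >= 1")
  structure(list(seed_nodes = unique(seed_nodes), p = p,
                 runs = as.integer(runs), seed = as.integer(seed),
                 weighted = weighted),
            class = "cascade_config")
}

edge_probabilities <- function(net, cfg) {
  if (cfg$weighted) pmin(1, cfg$p * net$edges$weight)
  else rep(cfg$p, nrow(net$edges))
}

# Per-run spread counts from surviving seeds, optionally under node removal.
# The retention draws depend only on (net, cfg), never on the removal set,
# which is what makes arm comparisons use common random numbers.
percolation_spreads <- function(net, cfg, removal = character()) {
  check_network(net)
  check_known_nodes(net, cfg$seed_nodes)
  nodes <- net$nodes
  n <- length(nodes)
  seeds <- setdiff(cfg$seed_nodes, removal)
  seed_idx <- match(seeds, nodes)

  probs <- edge_probabilities(net, cfg)
  m <- length(probs)
  keep_mat <- if (m > 0L) {
    with_seed(cfg$seed, matrix(stats::runif(m * cfg$runs), nrow = m) < probs)
  } else matrix(logical(), nrow = 0L, ncol = cfg$runs)

  removed <- nodes %in% removal
  from <- match(net$edges$source, nodes)
  to <- match(net$edges$target, nodes)
  usable <- !(removed[from] | removed[to])

  spreads <- integer(cfg$runs)
  if (!length(seed_idx)) return(spreads) # all seeds neutralised
  for (r in seq_len(cfg$runs)) {
    active <- logical(n)
    active[seed_idx] <- TRUE
    if (m > 0L) {
      keep <- keep_mat[, r] & usable
      repeat {
        reach <- keep & active[from] & !active[to]
        if (!any(reach)) break
        active[to[reach]] <- TRUE
      }
    }
    spreads[r] <- sum(active)
  }
  spreads
}

#' Simulate an independent cascade
#'
#' Runs the independent-cascade diffusion model from the configured seed
#' nodes: every newly activated node attempts once to activate each
#' inactive out-neighbour with the edge's transmission probability, until
#' quiescence. Spread is the activated-node count including seeds.
#' Implemented through the exact bond-percolation equivalence (per-run edge
#' retention + reachability), so `p = 1` reduces to deterministic
#' reachability and results are reproducible from the seed.
#'
#' @param net an `interaction_network`.
#' @param cfg a [cascade_config()].
#' @return a `cascade_result`: `mean`, `se` (standard error of the mean),
#'   and the per-run `spreads`.
#' @export
simulate_cascade <- function(net, cfg) {
  stopifnot(inherits(cfg, "cascade_config"))
  spreads <- percolation_spreads(net, cfg)
  structure(list(mean = mean(spreads),
                 se = stats::sd(spreads) / sqrt(length(spreads)),
                 spreads = spreads, config = cfg),
            class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("<cascade_result> mean spread %.2f +/- %.3f (%d runs, p = %g)\n",
              x$mean, x$se, length(x$spreads), x$config$p))
  invisible(x)
}

#' Removal set from centrality rankings
#'
#' Builds the node set to neutralise: the top-k of one metric, or the union
#' of top-k lists across several metrics (the traditional-vs-combined
#' contrast).
#'
#' @param rankings a `score_vector` or a list of them.
#' @param strategy `"single-metric"` or `"union-of-metrics"`.
#' @param k top-list size per metric.
#' @return character vector of node ids.
#' @export
removal_set_from_ranking <- function(rankings,
                                     strategy = c("single-metric",
                                                  "union-of-metrics"),
                                     k = 10L) {
  strategy <- match.arg(strategy)
  if (inherits(rankings, "score_vector")) rankings <- list(rankings)
  if (strategy == "single-metric") {
    as.character(top_k(rankings[[1L]], k))
  } else {
    sort(unique(unlist(lapply(rankings, top_k, k = k))), method = "radix")
  }
}

#' Evaluate a node-removal intervention
#'
#' Compares cascade spread on the intact network against spread after
#' removing a node set. Removed seed nodes are neutralised (deplatformed):
#' they cannot activate anyone. Both arms share the same random-number
#' draws, so the reduction estimate is not inflated by Monte-Carlo noise.
#' If the removal neutralises every seed the post-removal spread is 0 and
#' the 100% reduction is flagged, not an error.
#'
#' @param net an `interaction_network`.
#' @param cfg a [cascade_config()].
#' @param removal character vector of nodes to remove (subset of the
#'   network's nodes).
#' @param strategy_label label carried into reports.
#' @return an `intervention_outcome`: baseline and post-removal mean spread
#'   with standard errors, `reduction_percent`, the removal set and flags.
#' @export
evaluate_intervention <- function(net, cfg, removal,
                                  strategy_label = "removal") {
  stopifnot(inherits(cfg, "cascade_config"))
  removal <- unique(clean_id(as.character(removal)))
  check_known_nodes(net, removal)
  base <- percolation_spreads(net, cfg)
  post <- percolation_spreads(net, cfg, removal = removal)
  all_seeds_removed <- length(setdiff(cfg$seed_nodes, removal)) == 0L
  mb <- mean(base); mp <- mean(post)
  structure(list(baseline_spread = mb,
                 baseline_se = stats::sd(base) / sqrt(length(base)),
                 post_removal_spread = mp,
                 post_removal_se = stats::sd(post) / sqrt(length(post)),
                 reduction_percent = 100 * (1 - mp / mb),
                 removal_set = removal,
                 strategy_label = strategy_label,
                 all_seeds_removed = all_seeds_removed,
                 config = cfg),
            class = "intervention_outcome")
}

#' @export
print.intervention_outcome <- function(x, ...) {
  cat(sprintf("<intervention_outcome> %s: %.2f -> %.2f spread (%.1f%% reduction%s)\n",
              x$strategy_label, x$baseline_spread, x$post_removal_spread,
              x$reduction_percent,
              if (x$all_seeds_removed) ", all seeds removed" else ""))
  invisible(x)
}

#' Compare several removal strategies under common random numbers
#'
#' Evaluates each labelled removal set with the identical cascade draws and
#' returns the outcomes sorted by achieved reduction, a layered-defence view
#' of which targeting strategy suppresses spread most.
#'
#' @param net an `interaction_network`.
#' @param cfg a [cascade_config()].
#' @param strategies named list (>= 2, unique labels) of removal sets.
#' @return data frame `strategy`, `baseline`, `post_removal`,
#'   `reduction_percent` sorted by reduction (full outcomes in the
#'   `outcomes` attribute).
#' @export
strategy_comparison <- function(net, cfg, strategies) {
  if (!is.list(strategies) || length(strategies) < 2L) {
    stop_misinfluence("need at least 2 labelled strategies")
  }
  nms <- names(strategies)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms)) {
    stop_misinfluence("strategy labels must be present and unique")
  }
  outcomes <- lapply(nms, function(nm) {
    evaluate_intervention(net, cfg, strategies[[nm]], strategy_label = nm)
  })
  names(outcomes) <- nms
  tab <- data.frame(
    strategy = nms,
    baseline = vapply(outcomes, `[[`, numeric(1L), "baseline_spread"),
    post_removal = vapply(outcomes, `[[`, numeric(1L), "post_removal_spread"),
    reduction_percent = vapply(outcomes, `[[`, numeric(1L), "reduction_percent"),
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$reduction_percent, tab$strategy, method = "radix"), ]
  rownames(tab) <- NULL
  attr(tab, "outcomes") <- outcomes
  tab
}
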
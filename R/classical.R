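# The four classical centrality baselines on the directed interaction graph:
# degree, closeness (with a harmonic fallback for fragmented graphs),
# betweenness, and eigenvector centrality via power iteration.

check_nonempty <- function(net) {
  check_network(net)
  if (length(net$nodes) == 0L) stop_misinfluence("empty network")
  net
}

#' Degree centrality
#'
#' `C_D(v) = deg(v)`: the raw count of distinct edges incident to `v` under
#' the chosen direction. On a directed graph the in- and out-degree variants
#' count incoming and outgoing edges respectively. Scores are unnormalised
#' counts, as conventional for baseline reporting.
#'
#' @param net an `interaction_network`.
#' @param mode `"in"`, `"out"` or `"total"` degree.
#' @return a `score_vector`.
#' @export
degree_centrality <- function(net, mode = c("total", "in", "out")) {
  check_nonempty(net)
  mode <- match.arg(mode)
  deg <- degree_of(net, mode = mode)
  score_vector(as.numeric(deg) |> stats::setNames(names(deg)),
               metric = "degree", params = list(mode = mode))
}

# hop-count or inverse-weight distance matrix; rows are sources when
# direction = "outgoing" (distances *from* each node)
distance_matrix <- function(net, direction = "outgoing", weighted = FALSE) {
  g <- as_igraph(net)
  w <- if (weighted) 1 / igraph::E(g)$weight else NA
  igraph::distances(g, mode = if (direction == "outgoing") "out" else "in",
                    weights = w)
}

#' Closeness centrality with harmonic fallback
#'
#' Standard closeness is the reciprocal of the summed shortest-path
#' distances from `v` to every other node, `C_C(v) = 1 / sum d(v, u)`; it is
#' only defined when every node is reachable. On fragmented graphs -- the
#' norm in online misinformation settings -- the harmonic formulation
#' `H(v) = sum 1/d(v, u)` is used instead, with unreachable nodes
#' contributing zero. `formulation = "auto"` selects standard when every
#' ordered pair is reachable and harmonic otherwise, recording the choice in
#' the result's params.
#'
#' Distances are hop counts by default; in weighted mode each edge has
#' length `1/weight`, because weights are interaction strengths rather than
#' costs.
#'
#' @param net an `interaction_network`.
#' @param formulation `"auto"`, `"standard"` or `"harmonic"`.
#' @param direction `"outgoing"` (how quickly `v` reaches others) or
#'   `"incoming"`.
#' @param weighted use inverse-weight edge lengths.
#' @return a `score_vector`; `params$formulation_used` records the applied
#'   formulation.
#' @export
closeness_centrality <- function(net,
                                 formulation = c("auto", "standard", "harmonic"),
                                 direction = c("outgoing", "incoming"),
                                 weighted = FALSE) {
  check_nonempty(net)
  formulation <- match.arg(formulation)
  direction <- match.arg(direction)
  n <- length(net$nodes)
  D <- distance_matrix(net, direction, weighted)
  off <- D
  diag(off) <- NA
  all_reachable <- n == 1L || all(is.finite(off[!is.na(off)]))

  used <- formulation
  if (formulation == "auto") used <- if (all_reachable) "standard" else "harmonic"
  if (used == "standard" && !all_reachable) {
    stop_misinfluence("some ordered node pairs are unreachable; ",
                      "use formulation = 'harmonic' or 'auto'")
  }

  if (used == "standard") {
    tot <- rowSums(off, na.rm = TRUE)
    scores <- ifelse(tot > 0, 1 / tot, 0)
  } else {
    inv <- 1 / off
    inv[!is.finite(inv)] <- 0
    scores <- rowSums(inv, na.rm = TRUE)
  }
  score_vector(stats::setNames(as.numeric(scores), net$nodes),
               metric = "closeness",
               params = list(formulation = formulation,
                             formulation_used = used,
                             direction = direction, weighted = weighted))
}

#' Betweenness centrality
#'
#' `C_B(v) = sum over ordered pairs (s, t), s != t != v, of
#' sigma_st(v) / sigma_st`, where `sigma_st` counts shortest `s -> t` paths
#' and `sigma_st(v)` those passing through `v` as an interior node. Returned
#' as the raw (unnormalised) sum over ordered pairs, matching the directed
#' interaction graph. Computed with Brandes' accumulation algorithm (via
#' igraph). Unweighted mode uses hop counts; weighted mode uses edge length
#' `1/weight`.
#'
#' @param net an `interaction_network`.
#' @param weighted use inverse-weight edge lengths.
#' @return a `score_vector`.
#' @export
betweenness_centrality <- function(net, weighted = FALSE) {
  check_nonempty(net)
  g <- as_igraph(net)
  w <- if (weighted) {
    ew <- igraph::E(g)$weight
    if (any(ew <= 0)) stop_misinfluence("non-positive weight in weighted mode")
    1 / ew
  } else NA
  b <- igraph::betweenness(g, directed = TRUE, weights = w, normalized = FALSE)
  score_vector(stats::setNames(as.numeric(b), names(b))[net$nodes],
               metric = "betweenness", params = list(weighted = weighted))
}

spectral_summary <- function(dominant_eigenvalue, iterations_used, residual,
                             converged = TRUE) {
  structure(list(dominant_eigenvalue = dominant_eigenvalue,
                 iterations_used = iterations_used,
                 residual = residual, converged = converged),
            class = "spectral_summary")
}

#' @export
print.spectral_summary <- function(x, ...) {
  cat(sprintf("<spectral_summary> lambda=%s, iterations=%d, residual=%.3g, converged=%s\n",
              format(x$dominant_eigenvalue), x$iterations_used, x$residual,
              x$converged))
  invisible(x)
}

#' Eigenvector centrality by power iteration
#'
#' Power iteration on `M = t(A) + epsilon * J` (binary adjacency transposed,
#' so incoming links confer status, plus a uniform rank-one teleport
#' perturbation `epsilon * J` with `J` the all-ones matrix). The
#' perturbation makes `M` strictly positive, so by the Perron-Frobenius
#' theorem the dominant eigenvalue (Perron root) is real and positive with a
#' unique positive eigenvector -- guaranteeing a well-defined answer even on
#' fragmented or reducible graphs. The iteration itself runs on the shifted
#' operator `I + M`, which has the same eigenvectors but strictly separates
#' the Perron root from any complex eigenvalue of equal modulus, so cyclic
#' graph structures (where plain power iteration oscillates) still converge.
#' The returned vector is L2-normalised with all entries strictly positive.
#'
#' @param net an `interaction_network` with at least one edge.
#' @param tol convergence threshold on the L1 difference of successive
#'   iterates.
#' @param max_iter iteration cap; exceeding it is an error carrying the
#'   residual.
#' @param epsilon_teleport magnitude of the uniform perturbation.
#' @param mode `"in"` (status flows along incoming links, the default,
#'   consistent with the in-neighbour orientation of propagation centrality)
#'   or `"out"`.
#' @return list with components `scores` (a `score_vector`) and `summary`
#'   (a `spectral_summary` holding the Perron root estimate).
#' @export
eigenvector_centrality <- function(net, tol = 1e-9, max_iter = 1000L,
                                   epsilon_teleport = 1e-6,
                                   mode = c("in", "out")) {
  check_nonempty(net)
  mode <- match.arg(mode)
  if (nrow(net$edges) == 0L) {
    stop_misinfluence("eigenvector centrality requires at least one edge")
  }
  n <- length(net$nodes)
  A <- adjacency_matrix(net, weighted = FALSE)
  x <- rep(1 / sqrt(n), n)
  lambda <- NA_real_
  diff <- Inf
  for (it in seq_len(max_iter)) {
    y <- if (mode == "in") as.numeric(Matrix::crossprod(A, x)) else
      as.numeric(A %*% x)
    y <- y + epsilon_teleport * sum(x) + x # shifted operator I + M
    norm_shifted <- sqrt(sum(y^2))
    lambda <- norm_shifted - 1 # Perron root of M from a unit iterate
    x_new <- y / norm_shifted
    diff <- sum(abs(x_new - x))
    x <- x_new
    if (diff <= tol) {
      sv <- score_vector(stats::setNames(x, net$nodes), metric = "eigenvector",
                         params = list(tol = tol, max_iter = max_iter,
                                       epsilon_teleport = epsilon_teleport,
                                       mode = mode))
      return(list(scores = sv,
                  summary = spectral_summary(lambda, it, diff)))
    }
  }
  stop_misinfluence(sprintf(
    "eigenvector power iteration did not converge in %d iterations (residual %.3g)",
    max_iter, diff))
}
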
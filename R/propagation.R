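# Propagation centrality (PC): a damped, out-degree-normalised steady-state
# influence score in the PageRank family, oriented along incoming links.

#' Parameters for propagation centrality
#'
#' @param damping damping factor `d` in `(0, 1)`; the probability of
#'   following links rather than teleporting. Default 0.85, the conventional
#'   value for damped propagation ranking.
#' @param max_iter iteration cap; the update typically converges well within
#'   50--100 iterations at `d = 0.85`. Hitting the cap is flagged in the
#'   returned summary, not fatal.
#' @param tol convergence threshold on the L1 change between iterates.
#' @param dangling_mode `"literal"` drops the propagation mass of dangling
#'   (zero-out-degree) nodes exactly as the printed fixed-point equation
#'   does; `"redistribute"` adds it back uniformly, for comparability with
#'   conventional damped ranking.
#' @param weighted divide by out-strength (summed outgoing weights) instead
#'   of out-degree, weighting each contribution by its edge weight.
#' @return a `pc_params` list.
#' @export
pc_params <- function(damping = 0.85, max_iter = 100L, tol = 1e-9,
                      dangling_mode = c("literal", "redistribute"),
                      weighted = FALSE) {
  dangling_mode <- match.arg(dangling_mode)
  if (!is.numeric(damping) || damping <= 0 || damping >= 1) {
    stop_misinfluence("damping must lie strictly between 0 and 1")
  }
  if (max_iter < 1L) stop_misinfluence("max_iter must be >= 1")
  structure(list(damping = damping, max_iter = as.integer(max_iter),
                 tol = tol, dangling_mode = dangling_mode,
                 weighted = weighted), class = "pc_params")
}

#' Propagation centrality
#'
#' Computes the fixed point of
#' \deqn{x(v) = (1 - d)/n + d \sum_{u \in N_{in}(v)} x(u) / d_{out}(u)}
#' by iteration from the uniform vector `1/n`: each node shares its current
#' influence equally among its out-neighbours, damped by `d`, with a
#' `(1 - d)/n` teleport floor. Influence therefore accumulates recursively
#' -- an influential in-neighbour makes a node more influential -- and the
#' steady state ranks nodes by long-range propagation potential rather than
#' raw connectivity.
#'
#' Dangling nodes (zero out-degree) contribute nothing under the default
#' literal mode, so total mass may fall below 1 on graphs that have them;
#' `dangling_mode = "redistribute"` restores stochasticity by spreading
#' their mass uniformly.
#'
#' @param net a non-empty `interaction_network`.
#' @param params a [pc_params()] list.
#' @return list with `scores` (a `score_vector`) and `summary` (a
#'   `spectral_summary`; `converged = FALSE` flags hitting `max_iter`).
#' @examples
#' net <- interaction_network(data.frame(s = c("a", "a", "b"),
#'                                       t = c("b", "c", "c")))
#' propagation_centrality(net)$scores$scores # 0.05, 0.07125, 0.1318125
#' @export
propagation_centrality <- function(net, params = pc_params()) {
  check_nonempty(net)
  stopifnot(inherits(params, "pc_params"))
  n <- length(net$nodes)
  d <- params$damping

  A <- adjacency_matrix(net, weighted = params$weighted)
  outd <- if (params$weighted) out_strength(net) else
    as.numeric(degree_of(net, mode = "out"))
  dangling <- outd == 0
  scale <- ifelse(dangling, 0, 1 / pmax(outd, 1e-300))
  # B = D_out^{-1} A with zero rows for dangling nodes; update is t(B) %*% x
  B <- Matrix::Diagonal(x = scale) %*% A

  x <- rep(1 / n, n)
  teleport <- (1 - d) / n
  diff <- Inf
  it <- 0L
  for (it in seq_len(params$max_iter)) {
    x_new <- teleport + d * as.numeric(Matrix::crossprod(B, x))
    if (params$dangling_mode == "redistribute" && any(dangling)) {
      x_new <- x_new + d * sum(x[dangling]) / n
    }
    diff <- sum(abs(x_new - x))
    x <- x_new
    if (diff <= params$tol) break
  }
  converged <- diff <= params$tol
  if (!converged) {
    warning(sprintf("propagation centrality hit max_iter = %d (L1 residual %.3g)",
                    params$max_iter, diff), call. = FALSE)
  }
  sv <- score_vector(stats::setNames(x, net$nodes), metric = "pc",
                     params = list(damping = d, max_iter = params$max_iter,
                                   tol = params$tol,
                                   dangling_mode = params$dangling_mode,
                                   weighted = params$weighted))
  list(scores = sv,
       summary = spectral_summary(NA_real_, it, diff, converged))
}
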
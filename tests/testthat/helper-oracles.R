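# Fixture builders and independent oracles used across the suite. Oracles
# are deliberately naive (dense linear algebra, exhaustive enumeration) and
# share no code with the implementation paths they check.

make_net <- function(src, tgt, w = NULL, nodes = NULL) {
  df <- data.frame(source = src, target = tgt, stringsAsFactors = FALSE)
  if (!is.null(w)) df$weight <- w
  interaction_network(df, nodes = nodes)
}

random_digraph <- function(n, p = 0.3, weighted = FALSE, ensure_edge = TRUE) {
  ids <- sprintf("v%03d", seq_len(n))
  pairs <- expand.grid(s = seq_len(n), t = seq_len(n))
  pairs <- pairs[pairs$s != pairs$t, , drop = FALSE]
  keep <- stats::runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  if (!nrow(e) && ensure_edge) e <- data.frame(s = 1L, t = 2L)
  w <- if (weighted) round(stats::runif(nrow(e), 0.5, 3), 2) else rep(1, nrow(e))
  interaction_network(data.frame(source = ids[e$s], target = ids[e$t],
                                 weight = w, stringsAsFactors = FALSE),
                      nodes = ids)
}

# Direct linear solve of the damped propagation fixed point:
# (I - d * t(B)) x = (1 - d)/n, with B the out-degree-normalised adjacency
# and zero rows for dangling nodes (literal dangling handling).
oracle_pc_solve <- function(net, d = 0.85) {
  n <- length(net$nodes)
  A <- as.matrix(adjacency_matrix(net))
  outd <- rowSums(A)
  B <- A
  nz <- outd > 0
  B[nz, ] <- A[nz, , drop = FALSE] / outd[nz]
  x <- solve(diag(n) - d * t(B), rep((1 - d) / n, n))
  stats::setNames(as.numeric(x), net$nodes)
}

# Exhaustive betweenness: enumerate every simple path for every ordered
# pair by depth-first search, keep the shortest, and accumulate interior
# pass-through fractions.
oracle_betweenness_enum <- function(net) {
  nodes <- net$nodes
  adj <- lapply(nodes, function(v) net$edges$target[net$edges$source == v])
  names(adj) <- nodes
  bc <- stats::setNames(numeric(length(nodes)), nodes)
  for (s in nodes) for (t in nodes) {
    if (s == t) next
    found <- list()
    dfs <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        found[[length(found) + 1L]] <<- path
        return(invisible())
      }
      for (nb in adj[[last]]) if (!(nb %in% path)) dfs(c(path, nb))
    }
    dfs(s)
    if (!length(found)) next
    lens <- vapply(found, length, integer(1L))
    shortest <- found[lens == min(lens)]
    sigma <- length(shortest)
    interior <- unlist(lapply(shortest, function(p) p[-c(1L, length(p))]))
    if (length(interior)) {
      tb <- table(interior)
      bc[names(tb)] <- bc[names(tb)] + as.numeric(tb) / sigma
    }
  }
  bc
}

# Dominant eigenvector of the teleport-perturbed transposed adjacency from
# a dense full-spectrum solve.
oracle_eigen_dense <- function(net, eps = 1e-6) {
  A <- as.matrix(adjacency_matrix(net))
  M <- t(A) + eps
  e <- eigen(M)
  v <- Re(e$vectors[, which.max(Mod(e$values))])
  if (sum(v) < 0) v <- -v
  stats::setNames(v / sqrt(sum(v^2)), net$nodes)
}

# Cumulative influence via dense matrix powers: (I + t(A))^steps %*% 1.
oracle_dic_power <- function(net, steps) {
  A <- as.matrix(adjacency_matrix(net))
  M <- diag(length(net$nodes)) + t(A)
  x <- rep(1, length(net$nodes))
  for (i in seq_len(steps)) x <- as.numeric(M %*% x)
  stats::setNames(x, net$nodes)
}

# Literal vulnerability recurrence, step by step.
oracle_mvc_recurrence <- function(deg, vul0, steps) {
  v <- vul0
  for (i in seq_len(steps)) v <- deg * v
  v
}

# Seeded evaluation that restores the caller's RNG stream afterwards.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Reachable set from a seed set (igraph BFS), the p = 1 cascade oracle.
oracle_reachable <- function(net, seeds) {
  g <- igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                     vertices = net$nodes)
  out <- unique(unlist(lapply(seeds, function(s) {
    names(igraph::subcomponent(g, s, mode = "out"))
  })))
  sort(out)
}
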
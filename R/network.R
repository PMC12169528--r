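#' Construct a directed weighted interaction network
#'
#' The central data structure of the package: a directed graph `G = (V, E)`
#' whose nodes are opaque string identifiers (users) and whose edges carry a
#' strictly positive weight representing the strength or frequency of an
#' interaction (retweets, mentions, ...). Duplicate `(source, target)` rows
#' are merged by summing their weights, since weights count interactions;
#' self-loops are dropped (and counted in the load report) unless explicitly
#' permitted.
#'
#' @param edges a data frame (or matrix) whose first two columns are source
#'   and target identifiers and whose optional third column is a positive
#'   numeric weight (default 1).
#' @param nodes optional character vector of additional isolated nodes.
#' @param allow_self_loops keep `(v, v)` edges instead of dropping them.
#' @return an object of class `interaction_network` with components
#'   `nodes` (sorted identifiers), `edges` (merged edge table) and `report`
#'   (rows read, self-loops dropped, duplicates merged).
#' @examples
#' net <- interaction_network(data.frame(s = c("a", "a"), t = c("b", "b"),
#'                                       w = c(2, 3)))
#' net$edges$weight # 5
#' @export
interaction_network <- function(edges = NULL, nodes = NULL,
                                allow_self_loops = FALSE) {
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!is.data.frame(edges) || (nrow(edges) > 0L && ncol(edges) < 2L)) {
    stop_misinfluence("'edges' must be a data frame with >= 2 columns")
  }
  rows_read <- nrow(edges)
  if (rows_read > 0L) {
    src <- clean_id(as.character(edges[[1L]]))
    tgt <- clean_id(as.character(edges[[2L]]))
    w <- if (ncol(edges) >= 3L) as.numeric(edges[[3L]]) else rep(1, rows_read)
    if (anyNA(w) || any(w <= 0)) {
      stop_misinfluence("edge weights must be strictly positive numbers")
    }
    if (any(!nzchar(src)) || any(!nzchar(tgt))) {
      stop_misinfluence("empty node identifier in edge table")
    }
  } else {
    src <- tgt <- character()
    w <- numeric()
  }

  loops <- src == tgt
  self_loops_dropped <- 0L
  loop_nodes <- character()
  if (any(loops) && !allow_self_loops) {
    self_loops_dropped <- sum(loops)
    loop_nodes <- unique(src[loops])
    src <- src[!loops]; tgt <- tgt[!loops]; w <- w[!loops]
  }

  duplicates_merged <- 0L
  if (length(src)) {
    key <- paste(src, tgt, sep = "\r")
    duplicates_merged <- length(key) - length(unique(key))
    agg <- rowsum(w, group = key, reorder = TRUE)
    parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
    src_m <- vapply(parts, `[[`, character(1L), 1L)
    tgt_m <- vapply(parts, `[[`, character(1L), 2L)
    w_m <- as.numeric(agg[, 1L])
  } else {
    src_m <- tgt_m <- character(); w_m <- numeric()
  }

  # self-loop endpoints stay in the node set even when their edge is dropped
  all_nodes <- sort(unique(c(src_m, tgt_m, loop_nodes,
                             clean_id(as.character(nodes %||% character())))),
                    method = "radix")

  ord <- order(src_m, tgt_m, method = "radix")
  edge_tab <- data.frame(source = src_m[ord], target = tgt_m[ord],
                         weight = w_m[ord], stringsAsFactors = FALSE)
  rownames(edge_tab) <- NULL

  structure(
    list(nodes = all_nodes, edges = edge_tab,
         report = list(rows_read = rows_read,
                       self_loops_dropped = self_loops_dropped,
                       duplicates_merged = duplicates_merged)),
    class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / edges
#' @param net an `interaction_network`.
#' @return an integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

check_network <- function(net) {
  if (!inherits(net, "interaction_network")) {
    stop_misinfluence("expected an 'interaction_network' object")
  }
  net
}

check_known_nodes <- function(net, v) {
  unknown <- setdiff(v, net$nodes)
  if (length(unknown)) {
    stop_misinfluence("unknown node(s): ", paste(unknown, collapse = ", "))
  }
  invisible(v)
}

#' Adjacency matrix view
#'
#' Sparse adjacency matrix `A` with `a_ij = w_ij` for edge `i -> j`
#' (binary 0/1 when `weighted = FALSE`), rows and columns indexed by the
#' sorted node identifiers.
#'
#' @param net an `interaction_network`.
#' @param weighted use interaction weights instead of 0/1 indicators.
#' @return a `dgCMatrix`.
#' @export
adjacency_matrix <- function(net, weighted = FALSE) {
  check_network(net)
  n <- length(net$nodes)
  i <- match(net$edges$source, net$nodes)
  j <- match(net$edges$target, net$nodes)
  x <- if (weighted) net$edges$weight else rep(1, length(i))
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n),
                       dimnames = list(net$nodes, net$nodes))
}

as_igraph <- function(net) {
  check_network(net)
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = net$nodes)
}

#' In-neighbours of a node
#'
#' The set `N_in(v) = {u : (u, v) in E}` of sources with an edge into `v` --
#' the audience-facing side of a retweet graph and the summation set of both
#' the propagation-centrality and dynamic-influence updates.
#'
#' @param net an `interaction_network`.
#' @param v a node identifier present in the network.
#' @return sorted character vector of in-neighbour identifiers.
#' @export
in_neighbours <- function(net, v) {
  check_network(net)
  stopifnot(length(v) == 1L)
  check_known_nodes(net, v)
  sort(unique(net$edges$source[net$edges$target == v]), method = "radix")
}

#' @rdname in_neighbours
#' @export
out_neighbours <- function(net, v) {
  check_network(net)
  stopifnot(length(v) == 1L)
  check_known_nodes(net, v)
  sort(unique(net$edges$target[net$edges$source == v]), method = "radix")
}

#' Degree of one node or all nodes
#'
#' Counts distinct (merged) edges by direction; on a directed graph the total
#' degree is the sum of in- and out-degree.
#'
#' @param net an `interaction_network`.
#' @param v a node identifier, or `NULL` for a named vector over all nodes.
#' @param mode `"in"`, `"out"` or `"total"`.
#' @return integer count(s), named when `v` is `NULL`.
#' @export
degree_of <- function(net, v = NULL, mode = c("in", "out", "total")) {
  check_network(net)
  mode <- match.arg(mode)
  indeg <- tabulate(match(net$edges$target, net$nodes), nbins = length(net$nodes))
  outdeg <- tabulate(match(net$edges$source, net$nodes), nbins = length(net$nodes))
  deg <- switch(mode, "in" = indeg, out = outdeg, total = indeg + outdeg)
  names(deg) <- net$nodes
  if (is.null(v)) return(deg)
  check_known_nodes(net, v)
  deg[v]
}

# out-strength (sum of outgoing weights), used by the weighted PC variant
out_strength <- function(net) {
  s <- rowsum(net$edges$weight, group = net$edges$source)
  str <- stats::setNames(rep(0, length(net$nodes)), net$nodes)
  str[rownames(s)] <- s[, 1L]
  str
}

#' Remove nodes (simulated deplatforming)
#'
#' Returns the induced subgraph on the remaining nodes; every edge incident
#' to a removed node is deleted and the input network is left unmodified.
#'
#' @param net an `interaction_network`.
#' @param removal character vector of node identifiers, all present in `net`.
#' @return a new `interaction_network`.
#' @export
remove_nodes <- function(net, removal) {
  check_network(net)
  removal <- clean_id(as.character(removal))
  check_known_nodes(net, removal)
  keep_nodes <- setdiff(net$nodes, removal)
  keep <- !(net$edges$source %in% removal) & !(net$edges$target %in% removal)
  interaction_network(net$edges[keep, , drop = FALSE], nodes = keep_nodes)
}
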
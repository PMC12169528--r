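# Top-k influencer comparison: overlap partitioning across metric families,
# coverage-gain arithmetic, exclusivity fractions, and proxy-ground-truth
# rank alignment.

#' Top-k nodes of a score vector
#'
#' The `k` highest-scoring nodes, ties broken by ascending node id. When the
#' network has fewer than `k` nodes the full list is returned with a
#' `short_list` attribute set, a flagged success rather than an error.
#'
#' @param sv a `score_vector` or named numeric vector.
#' @param k list length (default 10, the conventional reporting size).
#' @return character vector of node ids in rank order.
#' @export
top_k <- function(sv, k = 10L) {
  if (k < 1L) stop_misinfluence("k must be >= 1")
  scores <- as_scores(sv)
  ord <- score_order(scores)
  out <- names(scores)[ord][seq_len(min(k, length(scores)))]
  attr(out, "short_list") <- length(scores) < k
  out
}

#' Partition the union of several top-k lists by exact membership
#'
#' Every node in the union of the given lists is assigned to exactly one
#' block keyed by the exact subset of lists that contain it: nodes shared by
#' all of `A`, `B`, `C` fall in `"A & B & C"`, nodes seen only in `A` in
#' `"A-exclusive"`. Blocks are pairwise disjoint and cover the union, so the
#' block counts always sum to the union size.
#'
#' @param lists a named list (>= 2 entries, unique names) of character
#'   vectors of node ids.
#' @return a `top_k_comparison`: `lists`, `partition` (label -> sorted node
#'   vector), `counts`, and `union_size`.
#' @export
overlap_partition <- function(lists) {
  if (!is.list(lists) || length(lists) < 2L) {
    stop_misinfluence("need at least 2 named lists")
  }
  nms <- names(lists)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms)) {
    stop_misinfluence("list names must be present and unique")
  }
  all_nodes <- sort(unique(unlist(lists, use.names = FALSE)), method = "radix")
  membership <- vapply(all_nodes, function(v) {
    members <- nms[vapply(lists, function(l) v %in% l, logical(1L))]
    if (length(members) == 1L) paste0(members, "-exclusive")
    else paste(members, collapse = " & ")
  }, character(1L))
  partition <- split(all_nodes, membership)
  partition <- lapply(partition, sort, method = "radix")
  structure(list(lists = lists, partition = partition,
                 counts = vapply(partition, length, integer(1L)),
                 union_size = length(all_nodes)),
            class = "top_k_comparison")
}

#' @export
print.top_k_comparison <- function(x, ...) {
  cat(sprintf("<top_k_comparison> %d lists, union %d nodes\n",
              length(x$lists), x$union_size))
  for (lbl in names(x$partition)) {
    cat(sprintf("  %-45s %2d  %s\n", lbl, x$counts[[lbl]],
                paste(x$partition[[lbl]], collapse = ", ")))
  }
  invisible(x)
}

#' Coverage gain from extending an influencer union
#'
#' The percentage increase in distinct influencers when a metric family is
#' extended: `100 * (|extended| - |base|) / |base|`, reported to two
#' decimals. Accepts either explicit node sets (the base must be a subset of
#' the extension) or bare counts, so printed summary figures can be checked
#' directly.
#'
#' @param base base union: character vector of ids, or a single count.
#' @param extended extended union, same form.
#' @return percentage, rounded to 2 decimals.
#' @examples
#' coverage_gain(29, 42) # 44.83
#' @export
coverage_gain <- function(base, extended) {
  if (is.character(base) || is.character(extended)) {
    stopifnot(is.character(base), is.character(extended))
    base <- unique(base); extended <- unique(extended)
    if (!all(base %in% extended)) {
      stop_misinfluence("base union must be a subset of the extended union")
    }
    nb <- length(base); ne <- length(extended)
  } else {
    nb <- as.numeric(base); ne <- as.numeric(extended)
  }
  if (nb <= 0) stop_misinfluence("base union must be non-empty")
  round(100 * (ne - nb) / nb, 2L)
}

#' Exclusivity of a candidate top-k list against reference lists
#'
#' The fraction of candidate nodes absent from every reference list
#' (and its complement, the overlap fraction). Quantifies how much of a
#' metric's top list is genuinely new relative to an existing family.
#'
#' @param candidate non-empty character vector of node ids.
#' @param reference_lists list of character vectors.
#' @return list with `exclusivity`, `overlap`, `exclusive_nodes`,
#'   `shared_nodes`.
#' @export
exclusivity_fraction <- function(candidate, reference_lists) {
  if (!length(candidate)) stop_misinfluence("candidate list is empty")
  ref <- unique(unlist(reference_lists, use.names = FALSE))
  exclusive <- !(candidate %in% ref)
  list(exclusivity = mean(exclusive), overlap = mean(!exclusive),
       exclusive_nodes = candidate[exclusive],
       shared_nodes = candidate[!exclusive])
}

#' Rank alignment between a metric and a proxy ground truth
#'
#' Compares a centrality score vector against an observable proxy for
#' influence or vulnerability (e.g. retweet counts, emotion-word counts):
#' the overlap fraction of the two top-k lists, and a Spearman rank
#' correlation computed literally as `1 - 6 * sum(d^2) / (n (n^2 - 1))` over
#' the full descending rankings, with midranks assigned to ties.
#'
#' @param sv a `score_vector`.
#' @param proxy named numeric vector covering every scored node (higher =
#'   stronger proxy signal).
#' @param k top-list size for the overlap component.
#' @param proxy_name label recorded in the result.
#' @return a `proxy_alignment`: `k`, `overlap_at_k`, `rank_correlation`,
#'   `proxy_name`.
#' @export
proxy_alignment <- function(sv, proxy, k = 10L, proxy_name = "proxy") {
  scores <- as_scores(sv)
  missing <- setdiff(names(scores), names(proxy))
  if (length(missing)) {
    stop_misinfluence("proxy values missing for node(s): ",
                      paste(missing, collapse = ", "))
  }
  proxy <- proxy[names(scores)]
  n <- length(scores)
  if (n < 2L) stop_misinfluence("need at least 2 nodes for rank alignment")

  k_eff <- min(k, n)
  overlap <- length(intersect(top_k(scores, k_eff), top_k(proxy, k_eff))) / k_eff

  r1 <- rank(-scores, ties.method = "average")
  r2 <- rank(-proxy, ties.method = "average")
  d <- r1 - r2
  rho <- 1 - 6 * sum(d^2) / (n * (n^2 - 1))

  structure(list(k = k_eff, overlap_at_k = overlap, rank_correlation = rho,
                 proxy_name = proxy_name),
            class = "proxy_alignment")
}

#' @export
print.proxy_alignment <- function(x, ...) {
  cat(sprintf("<proxy_alignment> vs %s: overlap@%d = %.2f, rho = %.3f\n",
              x$proxy_name, x$k, x$overlap_at_k, x$rank_correlation))
  invisible(x)
}

#' Count emotionally charged terms in a text
#'
#' Case-insensitive count of whole-token occurrences of lexicon entries
#' after splitting on non-alphanumeric characters, used to build the
#' emotion-word vulnerability proxy column. Token matching means "fearless"
#' does not count as "fear".
#'
#' @param text a character string (empty text counts 0).
#' @param lexicon non-empty character vector of terms; defaults to
#'   [default_emotion_lexicon()].
#' @return integer count of matching token occurrences.
#' @examples
#' count_emotion_terms("Fear, fear and outrage!") # 3
#' @export
count_emotion_terms <- function(text, lexicon = default_emotion_lexicon()) {
  if (!length(lexicon)) stop_misinfluence("lexicon must be non-empty")
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(0L)
  tokens <- strsplit(tolower(text), "[^[:alnum:]']+")[[1L]]
  tokens <- tokens[nzchar(tokens)]
  sum(tokens %in% tolower(lexicon))
}

#' Default emotion lexicon
#'
#' A 30-term synthetic lexicon covering fear, outrage and conspiracy
#' vocabulary, shipped as a plain-text fixture. It is a deliberately small,
#' non-canonical word list intended for exercising the proxy pipeline, not a
#' validated sentiment resource.
#'
#' @return character vector of lowercase terms.
#' @export
default_emotion_lexicon <- function() {
  path <- system.file("extdata", "emotion_lexicon_synthetic.txt",
                      package = "misinfluence", mustWork = TRUE)
  lines <- readLines(path, warn = FALSE)
  tolower(trimws(lines[!grepl("^\\s*(#|$)", lines)]))
}
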
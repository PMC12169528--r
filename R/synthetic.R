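# Seeded generator for retweet-style directed networks with planted
# structure: preferential-attachment growth (heavy-tailed in-degree),
# planted hubs (extra in-edges), planted vulnerable amplifiers (extra
# in-edges plus a vulnerability floor), and planted persistent spreaders
# (reciprocal echo-chamber cliques that inflate cumulative influence).

#' Specification for a synthetic misinformation network
#'
#' @param n node count of the growth component.
#' @param attachment_out out-edges per arriving node (each new user retweets
#'   this many existing users, chosen proportional to in-degree + 1).
#' @param planted_hubs number of planted structural hubs.
#' @param hub_boost in-edge margin for planted hubs: each hub receives extra
#'   in-edges (from distinct sources) until its in-degree exceeds the grown
#'   graph's natural maximum by this many edges, so hubs occupy the top
#'   in-degree ranks by construction.
#' @param planted_vulnerable number of planted vulnerable amplifiers: nodes
#'   given both an in-edge boost (`vulnerable_boost`, same margin semantics
#'   as `hub_boost`) and an initial vulnerability in `[vul_floor, 1]`,
#'   matching the profile of well-connected, credulous receivers.
#' @param vulnerable_boost in-edge margin per planted vulnerable node.
#' @param vul_floor lower bound of planted vulnerability draws; non-planted
#'   nodes draw from `U(0, vul_ceiling)` so planted nodes occupy the top
#'   vulnerability ranks by construction.
#' @param vul_ceiling upper bound of non-planted vulnerability draws.
#' @param planted_persistent number of planted persistent spreaders, each
#'   fed by a reciprocal echo-chamber clique of nine partner nodes whose
#'   mutual reinforcement compounds its cumulative influence.
#' @param misinfo_seed_fraction fraction of nodes flagged as misinformation
#'   originators.
#' @param islands number of disconnected reciprocal pairs appended (extra
#'   nodes), for exercising harmonic closeness on fragmented graphs.
#' @param seed integer seed; all outputs are reproducible bit-for-bit from
#'   `(spec, seed)`.
#' @return a `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 500L, attachment_out = 3L,
                           planted_hubs = 0L, hub_boost = 20L,
                           planted_vulnerable = 0L, vulnerable_boost = 20L,
                           vul_floor = 0.9, vul_ceiling = 0.85,
                           planted_persistent = 0L,
                           misinfo_seed_fraction = 0.05,
                           islands = 0L, seed = 1L) {
  if (attachment_out >= n) stop_misinfluence("attachment_out must be < n")
  if (attachment_out < 1L) stop_misinfluence("attachment_out must be >= 1")
  planted <- planted_hubs + planted_vulnerable + planted_persistent
  if (planted > n) stop_misinfluence("planted counts exceed n")
  if (misinfo_seed_fraction < 0 || misinfo_seed_fraction > 1) {
    stop_misinfluence("misinfo_seed_fraction must lie in [0, 1]")
  }
  if (vul_floor < 0 || vul_floor > 1 || vul_ceiling < 0 || vul_ceiling > 1) {
    stop_misinfluence("vulnerability bounds must lie in [0, 1]")
  }
  structure(list(n = as.integer(n), attachment_out = as.integer(attachment_out),
                 planted_hubs = as.integer(planted_hubs),
                 hub_boost = as.integer(hub_boost),
                 planted_vulnerable = as.integer(planted_vulnerable),
                 vulnerable_boost = as.integer(vulnerable_boost),
                 vul_floor = vul_floor, vul_ceiling = vul_ceiling,
                 planted_persistent = as.integer(planted_persistent),
                 misinfo_seed_fraction = misinfo_seed_fraction,
                 islands = as.integer(islands), seed = as.integer(seed)),
            class = "synthetic_spec")
}

# Sources of boost edges are drawn proportional to in-degree + 1, the same
# popularity rule as the growth process: planted hubs are retweeted by
# influential accounts as well as by the periphery, as real mega-hubs are.
boost_in_edges <- function(target, n_extra, existing_sources, n, indeg) {
  candidates <- setdiff(seq_len(n), c(target, existing_sources))
  sample(candidates, min(n_extra, length(candidates)),
         prob = indeg[candidates] + 1)
}

#' Generate a synthetic misinformation network with planted ground truth
#'
#' Grows a directed preferential-attachment graph (arriving nodes send
#' `attachment_out` retweet-style edges to existing nodes chosen
#' proportional to in-degree + 1, yielding a heavy-tailed in-degree
#' distribution), then wires in the planted structures declared by the
#' spec. Attributes are generated alongside: `vul0` (with planted floors),
#' `retweet_count` (rank-correlated with in-degree via bounded
#' multiplicative noise), `emotion_word_count` (rank-correlated with
#' `vul0`), and `misinfo_seed` flags. The manifest records every planted
#' identity so recovery tests have explicit ground truth.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `network` (an `interaction_network`), `attributes`
#'   (a `node_attribute_table`) and `manifest` (planted ids + the spec).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    n <- spec$n
    m <- spec$attachment_out
    total_nodes <- n + 2L * spec$islands
    width <- max(4L, nchar(as.character(total_nodes)))
    ids <- sprintf(paste0("n%0", width, "d"), seq_len(total_nodes))

    # seed core: a small directed cycle so attachment has targets
    m0 <- m + 1L
    src <- seq_len(m0)
    dst <- c(seq_len(m0)[-1L], 1L)
    indeg <- tabulate(dst, nbins = n)

    for (t in seq.int(m0 + 1L, n)) {
      targets <- sample(seq_len(t - 1L), m, prob = indeg[seq_len(t - 1L)] + 1)
      src <- c(src, rep(t, m))
      dst <- c(dst, targets)
      indeg[targets] <- indeg[targets] + 1L
    }

    available <- setdiff(seq_len(n), seq_len(m0))
    hubs <- if (spec$planted_hubs) sample(available, spec$planted_hubs) else integer()
    available <- setdiff(available, hubs)
    vulnerable <- if (spec$planted_vulnerable) {
      sample(available, spec$planted_vulnerable)
    } else integer()
    available <- setdiff(available, vulnerable)
    persistent <- if (spec$planted_persistent) {
      sample(available, spec$planted_persistent)
    } else integer()
    available <- setdiff(available, persistent)

    # Boosted nodes are lifted `boost` in-edges above the natural maximum of
    # the grown graph, so planted hubs occupy the top in-degree ranks by
    # construction rather than by chance.
    natural_max <- max(tabulate(dst, nbins = n))
    add_boost <- function(node, boost) {
      have <- sum(dst == node)
      extra <- natural_max - have + boost
      sources <- boost_in_edges(node, extra, src[dst == node], n,
                                tabulate(dst, nbins = n))
      src <<- c(src, sources)
      dst <<- c(dst, rep(node, length(sources)))
    }
    for (h in hubs) add_boost(h, spec$hub_boost)
    for (v in vulnerable) add_boost(v, spec$vulnerable_boost)

    # Persistent spreaders sit atop an insular echo chamber: nine partners
    # in a fully reciprocal clique (mutual-retweet community) all feeding
    # the planted node. Chamber members are rewired to interact only inside
    # the chamber (edges between them and the rest of the graph are
    # dropped), so the clique's geometrically compounding influence accrues
    # to the planted node and neither leaks into the attachment core nor
    # mixes with prior popularity. The planted node's cumulative influence
    # therefore overtakes the core within a few steps and stays on top --
    # the long-tail persistence profile -- while remaining strictly above
    # its partners, which do not hear back from it.
    for (p in persistent) {
      partners <- sample(available, 9L)
      available <- setdiff(available, partners)
      keep <- !(src %in% partners | dst %in% partners)
      src <- src[keep]
      dst <- dst[keep]
      prs <- t(utils::combn(partners, 2L))
      src <- c(src, prs[, 1L], prs[, 2L], partners)
      dst <- c(dst, prs[, 2L], prs[, 1L], rep(p, length(partners)))
    }

    if (spec$islands > 0L) {
      for (j in seq_len(spec$islands)) {
        a <- n + 2L * j - 1L
        b <- n + 2L * j
        src <- c(src, a, b)
        dst <- c(dst, b, a)
      }
    }

    net <- interaction_network(
      data.frame(source = ids[src], target = ids[dst], weight = 1,
                 stringsAsFactors = FALSE),
      nodes = ids)

    indeg_final <- degree_of(net, mode = "in")[ids]
    vul0 <- stats::runif(total_nodes) * spec$vul_ceiling
    vul0[vulnerable] <- spec$vul_floor +
      stats::runif(length(vulnerable)) * (1 - spec$vul_floor)
    retweet_count <- as.integer(round(
      10 * (as.numeric(indeg_final) + 1) * stats::runif(total_nodes, 0.8, 1.2)))
    emotion_word_count <- as.integer(round(
      50 * vul0 * stats::runif(total_nodes, 0.8, 1.2)))
    misinfo_seed <- stats::runif(total_nodes) < spec$misinfo_seed_fraction

    attrs <- node_attribute_table(data.frame(
      node_id = ids, vul0 = vul0, retweet_count = retweet_count,
      emotion_word_count = emotion_word_count, misinfo_seed = misinfo_seed,
      stringsAsFactors = FALSE))

    manifest <- list(spec = spec,
                     planted_hubs = sort(ids[hubs], method = "radix"),
                     planted_vulnerable = sort(ids[vulnerable], method = "radix"),
                     planted_persistent = sort(ids[persistent], method = "radix"),
                     island_nodes = if (spec$islands > 0L)
                       ids[seq.int(n + 1L, total_nodes)] else character())
    list(network = net, attributes = attrs, manifest = manifest)
  })
}

#' Worked five-node proxy-validation fixture
#'
#' A small bundle mirroring the shape of a published proxy-validation table:
#' five anonymised nodes with per-metric ranks, retweet counts
#' (200, 180, 90, 75, 50) and emotion-word counts (30, 45, 20, 15, 5),
#' plus score vectors derived from the ranks and a toy connecting network.
#' Exercises [proxy_alignment()] exactly as tabulated.
#'
#' @param dir optional directory; when given, `edges.csv` and
#'   `attributes.csv` are written there.
#' @return list with `attributes` (a `node_attribute_table` whose extra
#'   columns carry the printed ranks), `scores` (named list of
#'   `score_vector`s for pc/mvc/dic), `network`, and `proxies` (named
#'   numeric vectors `retweet_count`, `emotion_word_count`).
#' @export
generate_worked_fixture <- function(dir = NULL) {
  ids <- c("Node_A", "Node_B", "Node_C", "Node_D", "Node_E")
  ranks <- list(pc = c(1L, 2L, 5L, 3L, 4L),
                mvc = c(2L, 1L, 4L, 5L, 3L),
                dic = c(1L, 3L, 2L, 4L, 5L))
  retweet <- c(200L, 180L, 90L, 75L, 50L)
  emotion <- c(30L, 45L, 20L, 15L, 5L)

  attrs <- node_attribute_table(data.frame(
    node_id = ids, retweet_count = retweet, emotion_word_count = emotion,
    pc_rank = ranks$pc, mvc_rank = ranks$mvc, dic_rank = ranks$dic,
    stringsAsFactors = FALSE))

  scores <- lapply(names(ranks), function(metric) {
    score_vector(stats::setNames((6L - ranks[[metric]]) / 5, ids),
                 metric = metric, params = list(source = "worked_fixture"))
  })
  names(scores) <- names(ranks)

  edges <- data.frame(
    source = c("Node_A", "Node_A", "Node_B", "Node_C", "Node_D", "Node_E"),
    target = c("Node_B", "Node_C", "Node_A", "Node_A", "Node_B", "Node_D"),
    weight = c(3, 2, 2, 1, 1, 1), stringsAsFactors = FALSE)
  net <- interaction_network(edges)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(sprintf("%s,%s,%g", edges$source, edges$target, edges$weight),
               file.path(dir, "edges.csv"))
    utils::write.csv(as.data.frame(attrs), file.path(dir, "attributes.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(attributes = attrs, scores = scores, network = net,
       proxies = list(retweet_count = stats::setNames(as.numeric(retweet), ids),
                      emotion_word_count = stats::setNames(as.numeric(emotion), ids)))
}

#' Rebuild the published top-10 lists as data fixtures
#'
#' Reconstructs, from their printed categorisation, the four traditional
#' top-10 influencer lists (degree, eigenvector, betweenness, closeness) of
#' the COVID-19 misinformation case study, together with the
#' propagation-centrality top-10, the three vulnerability-exclusive nodes
#' and the dynamic-influence top-10. These are data fixtures (node-id lists
#' only, no graph) enabling overlap, coverage and exclusivity arithmetic to
#' be checked against the published counts.
#'
#' @return named list of character vectors: `degree`, `eigenvector`,
#'   `betweenness`, `closeness`, `pc`, `mvc_exclusive`, `dic`.
#' @export
rebuild_printed_toplists <- function() {
  list(
    degree = c("26", "756", "11019", "11248", "33091", "40327", "64409",
               "83247", "84148", "142153"),
    eigenvector = c("15", "26", "93", "102", "235", "522", "526", "593",
                    "756", "11248"),
    betweenness = c("2", "15", "26", "93", "102", "235", "522", "526",
                    "756", "1371"),
    closeness = c("4", "5", "6", "14", "28", "42", "43", "62", "66", "83"),
    pc = c("26", "11019", "11248", "15", "33091", "40327", "64409",
           "83247", "84148", "5398"),
    mvc_exclusive = c("101358", "72378", "130371"),
    dic = c("49905", "54048", "5958", "18119", "36077", "36393", "37557",
            "72479", "73960", "85735"))
}
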
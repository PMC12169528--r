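# Misinformation vulnerability centrality (MVC): degree-amplified
# susceptibility. A node's innate vulnerability vul_0 is multiplied by its
# (in-)degree at every timestep, so highly exposed, highly credulous
# receivers surface at the top after min-max normalisation.

#' Initialise per-node vulnerability
#'
#' Builds the `t = 0` vulnerability state from one of three sources, in
#' order of preference and with no silent mixing:
#'
#' 1. an explicit `vul0` column covering every network node;
#' 2. observable susceptibility features (`credibility`, `retweet_count`,
#'    `emotion_word_count`) covering every node -- each feature is min-max
#'    rescaled, the equal-weight mean is taken, and the result min-max
#'    rescaled again (a low credibility score, heavy unchecked retweeting
#'    and heavy emotional language all proxy susceptibility);
#' 3. a seeded `U(0, 1)` draw per node, consumed in ascending node-id order
#'    so the same seed reproduces the same vector on any platform.
#'
#' @param net an `interaction_network`.
#' @param attrs optional `node_attribute_table`.
#' @param seed integer seed for the uniform fallback; required when no
#'   usable attribute columns are supplied.
#' @return a `vulnerability_state` at `t = 0` with components `vul` (named
#'   vector in `[0, 1]`), `t`, `trajectory` and `source`.
#' @export
initialise_vulnerability <- function(net, attrs = NULL, seed = NULL) {
  check_network(net)
  nodes <- net$nodes
  n <- length(nodes)

  pick_col <- function(col) {
    if (is.null(attrs) || !col %in% names(attrs)) return(NULL)
    v <- attrs[[col]][match(nodes, attrs$node_id)]
    if (anyNA(v)) {
      missing <- nodes[is.na(v)]
      stop_misinfluence("attribute '", col, "' does not cover node(s): ",
                        paste(utils::head(missing, 5L), collapse = ", "),
                        if (length(missing) > 5L) ", ..." else "")
    }
    as.numeric(v)
  }

  if (!is.null(attrs) && "vul0" %in% names(attrs)) {
    vul <- pick_col("vul0")
    source <- "attributes"
  } else {
    feature_cols <- intersect(c("credibility", "retweet_count",
                                "emotion_word_count"), names(attrs %||% list()))
    if (length(feature_cols)) {
      feats <- vapply(feature_cols, pick_col, numeric(n))
      feats <- matrix(feats, nrow = n)
      scaled <- apply(feats, 2L, minmax_scale)
      scaled <- matrix(scaled, nrow = n)
      vul <- minmax_scale(rowMeans(scaled))
      source <- paste0("features(", paste(feature_cols, collapse = "+"), ")")
    } else {
      if (is.null(seed)) {
        stop_misinfluence("no vulnerability source: supply attrs with vul0 or ",
                          "feature columns, or a seed for the uniform draw")
      }
      vul <- with_seed(seed, stats::runif(n))
      source <- sprintf("seeded_uniform(%d)", as.integer(seed))
    }
  }
  names(vul) <- nodes
  structure(list(vul = vul, t = 0L,
                 trajectory = matrix(vul, ncol = 1L,
                                     dimnames = list(nodes, "t0")),
                 degree_mode = NA_character_, source = source),
            class = "vulnerability_state")
}

#' @export
print.vulnerability_state <- function(x, ...) {
  cat(sprintf("<vulnerability_state> n=%d, t=%d, source=%s\n",
              length(x$vul), x$t, x$source))
  invisible(x)
}

#' Misinformation vulnerability centrality
#'
#' Iterates the update `vul_{t+1}(v) = degree(v) * vul_t(v)` for a small
#' number of timesteps (default 5) and min-max normalises the final scores
#' to `[0, 1]`. Because the degree is fixed on a static snapshot, the
#' recurrence has the closed form `degree(v)^steps * vul_0(v)`, which is
#' what this function evaluates -- in log space, since the raw sequence
#' grows geometrically for degree > 1 and would overflow well before large
#' step counts. Min-max normalisation is invariant to a positive rescaling,
#' so the normalised result is identical to normalising the literal
#' recurrence output.
#'
#' The default `degree_mode = "in"` counts the sources that can reach a
#' node: vulnerability is amplified by exposure. Use `"out"` or `"total"` to
#' model broadcast-type influence instead. Note that `steps` acts as an
#' exposure weight: each extra step multiplies by degree once more, so
#' larger values tilt the ranking further towards connectivity and away
#' from innate susceptibility (two nodes whose degree and vulnerability
#' orderings disagree can swap ranks as `steps` grows). The default of 5
#' sits at the lower end of the typical five-to-ten range, keeping both
#' ingredients visible. What always holds is the dominance order: a node
#' with at least the degree and at least the vulnerability of another never
#' ranks below it, at any step count.
#'
#' @param net an `interaction_network`.
#' @param init a `vulnerability_state` from [initialise_vulnerability()].
#' @param steps number of amplification steps, between 1 and `max_steps`.
#' @param degree_mode `"in"`, `"out"` or `"total"`.
#' @param max_steps configurable ceiling on `steps`.
#' @return list with `scores` (min-max normalised `score_vector`) and
#'   `trajectory` (a `vulnerability_state` carrying the raw per-step
#'   matrix; entries overflow to `Inf` only beyond double range, the
#'   normalised scores never do).
#' @examples
#' net <- interaction_network(data.frame(s = c("a", "b"), t = c("c", "c")))
#' init <- initialise_vulnerability(net, seed = 1)
#' mvc <- misinformation_vulnerability_centrality(net, init, steps = 3)
#' @export
misinformation_vulnerability_centrality <- function(net, init, steps = 5L,
                                                    degree_mode = c("in", "out", "total"),
                                                    max_steps = 10L) {
  check_nonempty(net)
  stopifnot(inherits(init, "vulnerability_state"))
  degree_mode <- match.arg(degree_mode)
  if (steps < 1L) stop_misinfluence("steps must be >= 1")
  if (steps > max_steps) {
    stop_misinfluence("steps exceeds the configured ceiling (", max_steps, ")")
  }
  if (!identical(names(init$vul), net$nodes)) {
    stop_misinfluence("vulnerability state does not cover exactly the network's nodes")
  }
  deg <- as.numeric(degree_of(net, mode = degree_mode))
  vul0 <- as.numeric(init$vul)

  # closed form in log space: log raw = steps*log(deg) + log(vul0)
  lograw <- steps * log(deg) + log(vul0) # -Inf where deg or vul0 is 0
  m <- suppressWarnings(max(lograw[is.finite(lograw)]))
  if (!is.finite(m)) {
    normalised <- rep(0.5, length(vul0)) # every raw score is 0: degenerate
  } else {
    scaled <- exp(lograw - m) # in [0, 1], exact up to one rounding
    scaled[is.infinite(lograw) & lograw < 0] <- 0
    normalised <- minmax_scale(scaled)
  }

  traj <- vapply(0:steps, function(t) deg^t * vul0,
                 numeric(length(vul0)))
  traj <- matrix(traj, nrow = length(vul0),
                 dimnames = list(net$nodes, paste0("t", 0:steps)))

  sv <- score_vector(stats::setNames(normalised, net$nodes), metric = "mvc",
                     params = list(steps = as.integer(steps),
                                   degree_mode = degree_mode,
                                   source = init$source),
                     normalised = TRUE, normalisation = "minmax")
  state <- structure(list(vul = traj[, steps + 1L], t = as.integer(steps),
                          trajectory = traj, degree_mode = degree_mode,
                          source = init$source),
                     class = "vulnerability_state")
  list(scores = sv, trajectory = state)
}
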
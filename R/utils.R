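# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary, seeded RNG state
#'
#' Saves and restores `.Random.seed` so that library calls never disturb the
#' caller's random stream. All stochastic operations in the package route
#' through this helper, which is what makes them deterministic given a seed.
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a stage seed from a master seed and a stable label
#'
#' A small multiplicative string hash folded into the master seed, kept below
#' 2^31 so the result is a valid R integer seed. Used by the pipeline so that
#' stage-level reruns reproduce full-pipeline runs.
#' @param seed master integer seed.
#' @param label stable stage label, e.g. `"mvc"` or `"cascade"`.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
fork_seed <- function(seed, label) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147483646 + 1)
}

# Min-max rescaling to [0, 1]; a degenerate vector (all values equal) maps to
# the midpoint 0.5 rather than asserting universal extremes.
minmax_scale <- function(x, degenerate = 0.5) {
  rng <- range(x)
  if (rng[1] == rng[2]) return(rep(degenerate, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

# Deterministic ordering: descending score, ties broken by ascending node id
# in the C locale (radix) so results do not depend on platform collation.
score_order <- function(scores) {
  order(-scores, names(scores), method = "radix")
}

# Collapse internal whitespace in identifier fields ("11 019" -> "11019").
clean_id <- function(x) gsub("[[:space:]]+", "", x)

stop_misinfluence <- function(...) stop(..., call. = FALSE)
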
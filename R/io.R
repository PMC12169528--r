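# Readers and writers for the package's delimited text formats: edge lists,
# node attribute tables, and score files. All formats are plain text;
# '#'-prefixed lines are comments; the delimiter (tab or comma) is
# auto-detected from the first data row unless given explicitly.

detect_delim <- function(line) if (grepl("\t", line, fixed = TRUE)) "\t" else ","

#' Read a directed weighted edge list
#'
#' Parses a delimited text file with rows `source,target[,weight]` into an
#' [interaction_network()]. Missing weights default to 1. Duplicate
#' `(source, target)` rows are merged by summing weights; self-loops are
#' dropped unless `allow_self_loops = TRUE`. Internal whitespace inside
#' identifier fields is stripped, so dataset dialects that print grouped
#' digits ("11 019") load as a single id.
#'
#' @param path path to the edge-list file.
#' @param delimiter field separator; `NULL` auto-detects tab vs comma.
#' @param has_header skip the first data row.
#' @param allow_self_loops keep `(v, v)` edges.
#' @return an `interaction_network`; its `report` component (also available
#'   via [load_report()]) records rows read, self-loops dropped and
#'   duplicates merged.
#' @export
read_edge_list <- function(path, delimiter = NULL, has_header = FALSE,
                           allow_self_loops = FALSE) {
  if (!file.exists(path)) stop_misinfluence("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  data_idx <- which(keep)
  if (has_header && length(data_idx)) data_idx <- data_idx[-1L]
  if (!length(data_idx)) stop_misinfluence("empty edge-list file: ", path)
  delimiter <- delimiter %||% detect_delim(lines[data_idx[1L]])

  fields <- strsplit(lines[data_idx], delimiter, fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 2L | nf > 3L)
  if (length(bad)) {
    stop_misinfluence(sprintf("malformed row at line %d: expected 2 or 3 fields, got %d",
                              data_idx[bad[1L]], nf[bad[1L]]))
  }
  src <- vapply(fields, `[[`, character(1L), 1L)
  tgt <- vapply(fields, `[[`, character(1L), 2L)
  w <- rep(1, length(fields))
  has_w <- nf == 3L
  if (any(has_w)) {
    w[has_w] <- suppressWarnings(as.numeric(vapply(fields[has_w], `[[`,
                                                   character(1L), 3L)))
  }
  bad_w <- which(is.na(w) | w <= 0)
  if (length(bad_w)) {
    stop_misinfluence(sprintf("non-positive or non-numeric weight at line %d",
                              data_idx[bad_w[1L]]))
  }
  interaction_network(data.frame(source = src, target = tgt, weight = w,
                                 stringsAsFactors = FALSE),
                      allow_self_loops = allow_self_loops)
}

#' Load report of a parsed edge list
#' @param net an `interaction_network`.
#' @return list with `rows_read`, `self_loops_dropped`, `duplicates_merged`.
#' @export
load_report <- function(net) check_network(net)$report

#' Read a node attribute table
#'
#' A delimited file with a header; the `node_id` column is mandatory.
#' Recognised columns are validated and coerced: `vul0` (initial
#' vulnerability, numeric in `[0, 1]`), `retweet_count` and
#' `emotion_word_count` (non-negative integers), `misinfo_seed` (logical).
#' Unrecognised columns are preserved as opaque extras.
#'
#' @param path path to the attribute file.
#' @param delimiter field separator; `NULL` auto-detects tab vs comma.
#' @return a `node_attribute_table` (a validated data frame).
#' @export
read_node_attributes <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop_misinfluence("file not found: ", path)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[!grepl("^\\s*(#|$)", first)]
  if (!length(first)) stop_misinfluence("empty attribute file: ", path)
  delimiter <- delimiter %||% detect_delim(first[1L])
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          comment.char = "#", colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"")
  node_attribute_table(df)
}

#' Construct a node attribute table from a data frame
#'
#' @param df data frame with a `node_id` column and any of the recognised
#'   attribute columns (`vul0`, `retweet_count`, `emotion_word_count`,
#'   `misinfo_seed`).
#' @return a `node_attribute_table`.
#' @export
node_attribute_table <- function(df) {
  if (!"node_id" %in% names(df)) {
    stop_misinfluence("attribute table must have a 'node_id' column")
  }
  df$node_id <- clean_id(as.character(df$node_id))
  dup <- df$node_id[duplicated(df$node_id)]
  if (length(dup)) {
    stop_misinfluence("duplicate node_id: ", paste(unique(dup), collapse = ", "))
  }
  if ("vul0" %in% names(df)) {
    df$vul0 <- as.numeric(df$vul0)
    bad <- df$node_id[!is.na(df$vul0) & (df$vul0 < 0 | df$vul0 > 1)]
    if (length(bad)) {
      stop_misinfluence("vul0 outside [0,1] for node(s): ",
                        paste(bad, collapse = ", "))
    }
  }
  for (col in c("retweet_count", "emotion_word_count")) {
    if (col %in% names(df)) {
      df[[col]] <- as.numeric(df[[col]])
      bad <- df$node_id[!is.na(df[[col]]) &
                          (df[[col]] < 0 | df[[col]] != floor(df[[col]]))]
      if (length(bad)) {
        stop_misinfluence(col, " must be a non-negative integer; offending node(s): ",
                          paste(bad, collapse = ", "))
      }
      df[[col]] <- as.integer(df[[col]])
    }
  }
  if ("misinfo_seed" %in% names(df)) {
    v <- tolower(as.character(df$misinfo_seed))
    df$misinfo_seed <- v %in% c("true", "t", "1", "yes")
  }
  rownames(df) <- NULL
  class(df) <- c("node_attribute_table", "data.frame")
  df
}

#' Construct a score vector
#'
#' A node-to-score mapping tagged with the metric's name and the parameters
#' of the run that produced it, so every downstream artifact can state its
#' provenance.
#'
#' @param scores named numeric vector (names are node identifiers).
#' @param metric metric label, e.g. `"pc"`.
#' @param params named list of run parameters.
#' @param normalised logical; were the scores rescaled?
#' @param normalisation `"minmax"`, `"max"` or `NA`.
#' @return an object of class `score_vector`.
#' @export
score_vector <- function(scores, metric, params = list(),
                         normalised = FALSE, normalisation = NA_character_) {
  stopifnot(is.numeric(scores), !is.null(names(scores)),
            !anyNA(names(scores)), !any(duplicated(names(scores))))
  scores <- scores[order(names(scores), method = "radix")]
  structure(list(metric = metric, params = params, scores = scores,
                 normalised = normalised, normalisation = normalisation),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  cat(sprintf("<score_vector> metric=%s, n=%d, normalised=%s\n",
              x$metric, length(x$scores), x$normalised))
  invisible(x)
}

as_scores <- function(sv) {
  if (inherits(sv, "score_vector")) return(sv$scores)
  stopifnot(is.numeric(sv), !is.null(names(sv)))
  sv
}

#' Rank table of a score vector
#'
#' Rank 1 is the highest score; ties are broken deterministically by
#' ascending node identifier, so top-k lists are reproducible.
#'
#' @param sv a `score_vector` or named numeric vector.
#' @return data frame `node_id`, `score`, `rank`.
#' @export
rank_table <- function(sv) {
  scores <- as_scores(sv)
  ord <- score_order(scores)
  data.frame(node_id = names(scores)[ord], score = unname(scores[ord]),
             rank = seq_along(scores), stringsAsFactors = FALSE)
}

#' Write / read score files
#'
#' Scores are persisted as delimited text with columns
#' `node_id,score,rank` and a `#` comment header echoing the metric name and
#' run parameters. Scores are printed with 15 significant digits so a
#' write-then-read round trip preserves them to at least 12 significant
#' digits.
#'
#' @param sv a `score_vector`.
#' @param path output (input) file path.
#' @return `write_scores` invisibly returns `path`; `read_scores` returns a
#'   `score_vector`.
#' @export
write_scores <- function(sv, path) {
  stopifnot(inherits(sv, "score_vector"))
  params <- if (length(sv$params)) {
    paste(names(sv$params), vapply(sv$params, function(p)
      paste(format(p, digits = 15), collapse = "|"), character(1L)),
      sep = "=", collapse = "; ")
  } else ""
  header <- c(sprintf("# metric: %s", sv$metric),
              sprintf("# params: %s", params),
              sprintf("# normalised: %s (%s)", sv$normalised, sv$normalisation))
  tab <- rank_table(sv)
  body <- sprintf("%s,%.15g,%d", tab$node_id, tab$score, tab$rank)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(header, "node_id,score,rank", body), con)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop_misinfluence("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  comments <- lines[grepl("^#", lines)]
  metric <- sub("^# metric:\\s*", "", grep("^# metric:", comments, value = TRUE))
  if (!length(metric)) metric <- "unknown"
  params_line <- sub("^# params:\\s*", "", grep("^# params:", comments, value = TRUE))
  params <- list()
  if (length(params_line) && nzchar(params_line[1L])) {
    for (kv in strsplit(params_line[1L], ";\\s*")[[1L]]) {
      parts <- strsplit(kv, "=", fixed = TRUE)[[1L]]
      if (length(parts) == 2L) params[[parts[1L]]] <- parts[2L]
    }
  }
  data_lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(data_lines) < 1L) stop_misinfluence("no header row in score file")
  data_lines <- data_lines[-1L] # drop the node_id,score,rank header
  if (!length(data_lines)) {
    return(score_vector(stats::setNames(numeric(), character()), metric[1L], params))
  }
  fields <- strsplit(data_lines, ",", fixed = TRUE)
  ids <- vapply(fields, `[[`, character(1L), 1L)
  vals <- as.numeric(vapply(fields, `[[`, character(1L), 2L))
  score_vector(stats::setNames(vals, ids), metric[1L], params)
}
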
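#' @keywords internal
"_PACKAGE"

# Column contracts for the two CSV layouts.
.RESPONSE_COLS <- c("person_id", "item_id", "rater_id", "response_id", "rating")
.SCORE_COLS <- c("person_id", "item_id", "rater_id", "score")
.RATING_MIN <- 1
.RATING_MAX <- 5

#' Task families recognized by the toolkit
#'
#' Divergent-thinking prompts belong to one of two task families:
#' `"alternative_uses"` (creative uses for an everyday object, e.g. a brick
#' or a knife) and `"consequences"` (consequences of a counterfactual
#' scenario, e.g. people no longer needing sleep). The family facet is held
#' fixed: every analysis is run separately within a family, never pooled
#' across families.
#'
#' @return Character vector of the two family labels.
#' @export
task_families <- function() c("alternative_uses", "consequences")

.chk_family <- function(family) {
  bad <- setdiff(unique(as.character(family)), task_families())
  if (length(bad) > 0) {
    stop("unknown task family: ", paste(bad, collapse = ", "),
         " (expected one of: ", paste(task_families(), collapse = ", "), ")",
         call. = FALSE)
  }
}

.chk_rating_bounds <- function(x, what = "rating") {
  if (!is.numeric(x)) {
    stop(what, " column must be numeric", call. = FALSE)
  }
  bad <- which(!is.finite(x) | x < .RATING_MIN | x > .RATING_MAX)
  if (length(bad) > 0) {
    stop(what, " outside the scale bounds [", .RATING_MIN, ", ", .RATING_MAX,
         "] at row(s): ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' Construct a response-level ratings table
#'
#' One row per rating of one response by one rater: the raw datum of the
#' average-rating scoring system, in which every individual response a
#' person produces is rated on the 1-5 scale by every rater.
#'
#' @param df Data frame with columns `person_id`, `item_id`, `rater_id`,
#'   `response_id`, `rating`, and either a `family` column or none (in which
#'   case `item_map` must be supplied).
#' @param item_map Named character vector mapping `item_id` to task family;
#'   used to derive the `family` column when absent, and to check it when
#'   present.
#' @return A `response_ratings` data frame (columns `person_id`, `family`,
#'   `item_id`, `rater_id`, `response_id`, `rating`).
#' @export
response_ratings <- function(df, item_map = NULL) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(.RESPONSE_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$rating <- as.numeric(df$rating)
  .chk_rating_bounds(df$rating)
  df <- .apply_item_map(df, item_map)
  for (col in c("person_id", "item_id", "rater_id", "response_id")) {
    df[[col]] <- as.character(df[[col]])
  }
  key <- paste(df$person_id, df$item_id, df$rater_id, df$response_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate (person, item, rater, response) at row(s): ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  }
  .chk_item_single_family(df)
  out <- df[, c("person_id", "family", "item_id", "rater_id", "response_id",
                "rating")]
  rownames(out) <- NULL
  class(out) <- c("response_ratings", "data.frame")
  out
}

#' Construct a score-level table
#'
#' One score per (person, item, rater) cell: the unit of analysis of the
#' crossed p x i x r G-study. Scores are on the 1-5 scale but need not be
#' integers (averaged ratings rarely are).
#'
#' @inheritParams response_ratings
#' @param df Data frame with columns `person_id`, `item_id`, `rater_id`,
#'   `score`, plus `family` or an `item_map`.
#' @return A `score_table` data frame.
#' @export
score_table <- function(df, item_map = NULL) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(.SCORE_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df$score <- as.numeric(df$score)
  .chk_rating_bounds(df$score, what = "score")
  df <- .apply_item_map(df, item_map)
  for (col in c("person_id", "item_id", "rater_id")) {
    df[[col]] <- as.character(df[[col]])
  }
  .chk_item_single_family(df)
  out <- df[, c("person_id", "family", "item_id", "rater_id", "score")]
  rownames(out) <- NULL
  class(out) <- c("score_table", "data.frame")
  out
}

.apply_item_map <- function(df, item_map) {
  if (is.null(item_map)) {
    if (!"family" %in% names(df)) {
      stop("no 'family' column and no item_map to derive it from",
           call. = FALSE)
    }
  } else {
    if (is.null(names(item_map)) || any(names(item_map) == "")) {
      stop("item_map must be a named vector: names are item ids, values families",
           call. = FALSE)
    }
    unmapped <- setdiff(unique(as.character(df$item_id)), names(item_map))
    if (length(unmapped) > 0) {
      stop("item_map has no family for item(s): ",
           paste(unmapped, collapse = ", "), call. = FALSE)
    }
    df$family <- unname(item_map[as.character(df$item_id)])
  }
  df$family <- as.character(df$family)
  .chk_family(df$family)
  df
}

.chk_item_single_family <- function(df) {
  fam_per_item <- tapply(df$family, df$item_id, function(f) length(unique(f)))
  if (any(fam_per_item > 1)) {
    stop("item(s) mapped to more than one family: ",
         paste(names(fam_per_item)[fam_per_item > 1], collapse = ", "),
         call. = FALSE)
  }
  invisible(df)
}

#' Read a ratings CSV
#'
#' Reads a long-format UTF-8 CSV (header row, comma-separated) at either the
#' response level (columns `person_id`, `item_id`, `rater_id`, `response_id`,
#' `rating`) or the score level (`person_id`, `item_id`, `rater_id`,
#' `score`). A `family` column is taken as-is if present; otherwise it is
#' derived from `item_map`. Identifiers are opaque strings.
#'
#' @param path Path to the CSV file.
#' @param layout `"response_level"` or `"score_level"`.
#' @param item_map Named character vector item_id -> family, or a path to a
#'   YAML/CSV config readable by [read_item_map()].
#' @return A [response_ratings] or [score_table] object.
#' @export
load_ratings <- function(path, layout = c("response_level", "score_level"),
                         item_map = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  if (is.character(item_map) && length(item_map) == 1 && is.null(names(item_map)) &&
      file.exists(item_map)) {
    item_map <- read_item_map(item_map)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  num_col <- if (layout == "response_level") "rating" else "score"
  if (num_col %in% names(df)) {
    suppressWarnings(num <- as.numeric(df[[num_col]]))
    bad <- which(is.na(num) & !is.na(df[[num_col]]))
    if (length(bad) > 0) {
      stop("non-numeric ", num_col, " at row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    df[[num_col]] <- num
  }
  if (layout == "response_level") response_ratings(df, item_map = item_map)
  else score_table(df, item_map = item_map)
}

#' Read an item-to-family map from a config file
#'
#' Accepts either a YAML file of `item_id: family` pairs or a two-column CSV
#' with headers `item_id,family`.
#'
#' @param path Path to the config file.
#' @return Named character vector (names are item ids, values families).
#' @export
read_item_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML item maps requires the 'yaml' package", call. = FALSE)
    }
    lst <- yaml::read_yaml(path)
    map <- vapply(lst, as.character, character(1))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("item_id", "family") %in% names(df))) {
      stop("item map CSV needs columns item_id, family", call. = FALSE)
    }
    map <- stats::setNames(as.character(df$family), as.character(df$item_id))
  }
  .chk_family(map)
  map
}

#' Write a ratings or score table as CSV
#'
#' Inverse of [load_ratings()]: writes the long-format CSV dialect used
#' throughout (UTF-8, comma-separated, header row, no row names), so that a
#' write/load round trip reproduces the table exactly.
#'
#' @param x A `response_ratings`, `score_table`, or plain data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}

#' Measurement design of a score table
#'
#' Describes a crossed p x i x r design: the facet sample sizes and whether
#' the table is balanced-complete (exactly one score in every cell).
#'
#' @param n_p,n_i,n_r Counts of persons, items, raters (each >= 1).
#' @param balanced Logical: does every (person, item, rater) cell hold
#'   exactly one observation?
#' @return A `gt_design` list.
#' @export
gt_design <- function(n_p, n_i, n_r, balanced) {
  stopifnot(n_p >= 1, n_i >= 1, n_r >= 1, is.logical(balanced))
  structure(list(n_p = as.integer(n_p), n_i = as.integer(n_i),
                 n_r = as.integer(n_r), balanced = isTRUE(balanced)),
            class = "gt_design")
}

#' @export
print.gt_design <- function(x, ...) {
  cat(sprintf("Crossed p x i x r design: %d persons x %d items x %d raters (%s)\n",
              x$n_p, x$n_i, x$n_r,
              if (x$balanced) "balanced-complete" else "NOT balanced"))
  invisible(x)
}

#' Check a score table for balanced completeness
#'
#' A G-study by the expected-mean-squares method needs a fully crossed,
#' complete design: every person scored by every rater on every item,
#' exactly once. Duplicated cells are an error (they indicate a data
#' problem); missing cells yield `balanced = FALSE` and estimation
#' functions will refuse the table.
#'
#' The result is invariant to row order.
#'
#' @param scores A [score_table].
#' @return A [gt_design] with the observed facet counts.
#' @export
validate_balanced <- function(scores) {
  stopifnot(inherits(scores, "score_table") || is.data.frame(scores))
  if (nrow(scores) == 0) stop("score table is empty", call. = FALSE)
  key <- paste(scores$person_id, scores$item_id, scores$rater_id, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    cells <- utils::head(gsub("\r", " / ", dup), 5L)
    stop("duplicated (person, item, rater) cell(s): ",
         paste(cells, collapse = "; "), call. = FALSE)
  }
  n_p <- length(unique(scores$person_id))
  n_i <- length(unique(scores$item_id))
  n_r <- length(unique(scores$rater_id))
  gt_design(n_p, n_i, n_r, balanced = nrow(scores) == n_p * n_i * n_r)
}

#' Split a table by task family
#'
#' Every downstream analysis is run within one task family (the family
#' facet is fixed); this returns the per-family subtables, preserving class.
#'
#' @param x A `response_ratings` or `score_table`.
#' @return Named list of subtables, one per family present.
#' @export
split_by_family <- function(x) {
  out <- split(as.data.frame(x), x$family)
  lapply(out, function(d) {
    rownames(d) <- NULL
    class(d) <- class(x)
    d
  })
}
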
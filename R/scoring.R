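# Scoring systems: average creativity, snapshot, fluency, and the
# per-person composites used for convergent validity.

#' Average-rating scores from response-level ratings
#'
#' Under the average-rating system each individual response is rated 1-5 by
#' every rater; a person's score for an item, from one rater, is the
#' unweighted arithmetic mean of that rater's ratings over all of the
#' person's responses to that item. Responses are weighted equally
#' regardless of how many a person produced.
#'
#' If a (person, item) pair was rated by some raters but not others the
#' crossed design is broken and an error is raised.
#'
#' @param responses A [response_ratings] table.
#' @return A [score_table] with one row per (person, item, rater) cell that
#'   has at least one rating.
#' @export
average_rating_scores <- function(responses) {
  stopifnot(is.data.frame(responses))
  if (nrow(responses) == 0) stop("response table is empty", call. = FALSE)
  agg <- stats::aggregate(
    rating ~ person_id + family + item_id + rater_id,
    data = as.data.frame(responses), FUN = mean)
  names(agg)[names(agg) == "rating"] <- "score"
  # every rater must cover every (person, item) pair that any rater covers
  pi_key <- paste(agg$person_id, agg$item_id, sep = "\r")
  raters <- sort(unique(agg$rater_id))
  n_by_pi <- tapply(agg$rater_id, pi_key, function(r) length(unique(r)))
  incomplete <- names(n_by_pi)[n_by_pi != length(raters)]
  if (length(incomplete) > 0) {
    stop("incomplete cells: (person, item) pair(s) rated by only some raters: ",
         paste(utils::head(gsub("\r", " / ", incomplete), 5L), collapse = "; "),
         call. = FALSE)
  }
  agg <- agg[order(agg$person_id, agg$item_id, agg$rater_id), ]
  score_table(agg)
}

#' Validate a snapshot score table
#'
#' Under the snapshot system each rater awards a single holistic 1-5 rating
#' to a person's whole response set for an item, so no aggregation is
#' needed: this checks bounds and the one-score-per-cell definition and
#' passes the table through unchanged. Two snapshot rows for the same
#' (person, item, rater) cell violate the definition and raise an error.
#'
#' @param scores A [score_table] of snapshot ratings.
#' @return The validated [score_table], unchanged.
#' @export
snapshot_scores <- function(scores) {
  scores <- if (inherits(scores, "score_table")) scores else score_table(scores)
  key <- paste(scores$person_id, scores$item_id, scores$rater_id, sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    stop("snapshot scoring admits one rating per (person, item, rater) cell; ",
         "duplicated cell(s): ",
         paste(utils::head(gsub("\r", " / ", dup), 5L), collapse = "; "),
         call. = FALSE)
  }
  scores
}

#' Fluency scores from response-level data
#'
#' Fluency is the number of responses a person gave to a prompt; raters play
#' no role. Persons or items present in the table but absent for a given
#' (person, item) pair get fluency 0, so the output covers the full
#' person x item grid of the input.
#'
#' @param responses A [response_ratings] table.
#' @return A `fluency_table` data frame with columns `person_id`, `family`,
#'   `item_id`, `fluency`.
#' @export
fluency_scores <- function(responses) {
  stopifnot(is.data.frame(responses))
  df <- as.data.frame(responses)
  persons <- sort(unique(df$person_id))
  items <- unique(df[, c("item_id", "family")])
  items <- items[order(items$item_id), ]
  grid <- expand.grid(person_id = persons, item_id = items$item_id,
                      stringsAsFactors = FALSE)
  grid$family <- items$family[match(grid$item_id, items$item_id)]
  # distinct responses per (person, item); a response rated by several raters
  # counts once
  key <- paste(df$person_id, df$item_id, sep = "\r")
  counts <- tapply(df$response_id, key, function(r) length(unique(r)))
  gkey <- paste(grid$person_id, grid$item_id, sep = "\r")
  grid$fluency <- as.integer(ifelse(gkey %in% names(counts),
                                    counts[gkey], 0L))
  out <- grid[order(grid$person_id, grid$item_id),
              c("person_id", "family", "item_id", "fluency")]
  rownames(out) <- NULL
  class(out) <- c("fluency_table", "data.frame")
  out
}

#' Per-person composite scores for validity analysis
#'
#' Builds the per-person variables that enter the convergent-validity
#' correlation matrix. At `level = "per_item"` a person's score for an item
#' is the mean over raters of the cell scores; at `level = "per_family"`
#' those per-item means are averaged again over the family's items. Fluency
#' composites are the per-item counts, or their mean within a family.
#'
#' Variable names are `<system>_<item>` (per item) or `<system>_<family>`
#' (per family), e.g. `"average_brick"` or `"fluency_alternative_uses"`.
#'
#' @param scores A balanced [score_table], or `NULL` to build fluency-only
#'   composites.
#' @param fluency Optional `fluency_table` from [fluency_scores()].
#' @param level `"per_item"` or `"per_family"`.
#' @param system Label for the scoring system behind `scores`, used to name
#'   variables (e.g. `"average"`, `"snapshot"`).
#' @return A `composite_scores` data frame with columns `person_id`,
#'   `variable_name`, `value`; one row per (person, variable).
#' @export
composite_scores <- function(scores = NULL, fluency = NULL,
                             level = c("per_item", "per_family"),
                             system = "average") {
  level <- match.arg(level)
  if (is.null(scores) && is.null(fluency)) {
    stop("supply scores, fluency, or both", call. = FALSE)
  }
  pieces <- list()
  if (!is.null(scores)) {
    design <- validate_balanced(scores)
    if (!design$balanced) {
      stop("composite scoring requires a balanced score table", call. = FALSE)
    }
    df <- as.data.frame(scores)
    per_item <- stats::aggregate(score ~ person_id + family + item_id,
                                 data = df, FUN = mean)
    if (level == "per_item") {
      per_item$variable_name <- paste(system, per_item$item_id, sep = "_")
      pieces$scores <- per_item[, c("person_id", "variable_name", "score")]
    } else {
      per_fam <- stats::aggregate(score ~ person_id + family,
                                  data = per_item, FUN = mean)
      per_fam$variable_name <- paste(system, per_fam$family, sep = "_")
      pieces$scores <- per_fam[, c("person_id", "variable_name", "score")]
    }
    names(pieces$scores)[3] <- "value"
  }
  if (!is.null(fluency)) {
    fdf <- as.data.frame(fluency)
    if (level == "per_item") {
      fdf$variable_name <- paste("fluency", fdf$item_id, sep = "_")
      pieces$fluency <- fdf[, c("person_id", "variable_name", "fluency")]
    } else {
      per_fam <- stats::aggregate(fluency ~ person_id + family,
                                  data = fdf, FUN = mean)
      per_fam$variable_name <- paste("fluency", per_fam$family, sep = "_")
      pieces$fluency <- per_fam[, c("person_id", "variable_name", "fluency")]
    }
    names(pieces$fluency)[3] <- "value"
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$variable_name, out$person_id), ]
  rownames(out) <- NULL
  class(out) <- c("composite_scores", "data.frame")
  out
}
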
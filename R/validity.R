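# Convergent-validity descriptives: per-variable means and SDs and the
# Pearson correlation matrix across scoring systems and fluency.

#' Convergent-validity report
#'
#' Builds the descriptive table used to assess convergent validity across
#' scoring systems: per-variable sample mean and standard deviation
#' (n - 1 denominator) and the pairwise Pearson correlation matrix.
#' Complete cases are required: every variable must be observed for every
#' person. Variables are ordered by name (system, then item/family), so the
#' report is deterministic and stable under row permutation of the input.
#'
#' A zero-variance variable has no defined correlations; its pairs are
#' reported as `NA` with a warning.
#'
#' @param composites A [composite_scores] table (stack several with
#'   `rbind()` to combine systems), or a wide data frame of one column per
#'   variable with a `person_id` column.
#' @return A `validity_report` list: `descriptives` (data frame with
#'   `variable`, `mean`, `sd`), `correlations` (symmetric matrix, unit
#'   diagonal), `n` (number of persons).
#' @export
validity_report <- function(composites) {
  wide <- .composites_to_wide(composites)
  n <- nrow(wide)
  if (n < 3) {
    stop("validity report requires at least 3 persons, got ", n,
         call. = FALSE)
  }
  vars <- sort(setdiff(names(wide), "person_id"))
  mat <- as.matrix(wide[, vars, drop = FALSE])
  if (any(!is.finite(mat))) {
    stop("complete cases required: every variable observed for every person",
         call. = FALSE)
  }
  mu <- colMeans(mat)
  sd_ <- apply(mat, 2, stats::sd)
  degenerate <- vars[sd_ == 0]
  if (length(degenerate) > 0) {
    warning("zero-variance variable(s): ",
            paste(degenerate, collapse = ", "),
            "; their correlations are undefined and reported as NA",
            call. = FALSE)
  }
  cors <- suppressWarnings(stats::cor(mat, method = "pearson"))
  diag(cors) <- 1
  structure(list(
    descriptives = data.frame(variable = vars, mean = unname(mu),
                              sd = unname(sd_), row.names = NULL),
    correlations = cors,
    n = n
  ), class = "validity_report")
}

.composites_to_wide <- function(composites) {
  df <- as.data.frame(composites)
  if (all(c("person_id", "variable_name", "value") %in% names(df))) {
    key <- paste(df$person_id, df$variable_name, sep = "\r")
    if (anyDuplicated(key)) {
      stop("more than one value per (person, variable)", call. = FALSE)
    }
    wide <- stats::reshape(
      df[, c("person_id", "variable_name", "value")],
      idvar = "person_id", timevar = "variable_name", direction = "wide")
    names(wide) <- sub("^value\\.", "", names(wide))
    rownames(wide) <- NULL
    wide
  } else if ("person_id" %in% names(df)) {
    df
  } else {
    stop("expected long composite scores (person_id, variable_name, value) ",
         "or a wide table with a person_id column", call. = FALSE)
  }
}

#' @export
print.validity_report <- function(x, ...) {
  cat(sprintf("Convergent-validity report (N = %d persons)\n", x$n))
  d <- x$descriptives
  d$mean <- sprintf("%.2f", d$mean)
  d$sd <- sprintf("%.2f", d$sd)
  print(d, row.names = FALSE)
  cat("\nPearson correlations (2 decimals):\n")
  print(round(x$correlations, 2))
  invisible(x)
}

#' Write a validity report as CSV
#'
#' One row per variable: mean, SD, then the lower-triangular correlations
#' with the preceding variables, mirroring conventional descriptive tables.
#'
#' @param x A `validity_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validity_report <- function(x, path) {
  stopifnot(inherits(x, "validity_report"))
  vars <- x$descriptives$variable
  k <- length(vars)
  tri <- matrix("", k, k, dimnames = list(vars, vars))
  for (a in seq_len(k)) for (b in seq_len(a - 1)) {
    v <- x$correlations[vars[a], vars[b]]
    tri[a, b] <- ifelse(is.na(v), "NA", sprintf("%.2f", v))
  }
  out <- data.frame(variable = vars,
                    M = round(x$descriptives$mean, 2),
                    SD = round(x$descriptives$sd, 2),
                    tri, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
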
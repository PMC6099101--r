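# G-study: balanced three-way crossed ANOVA decomposition and the
# expected-mean-squares (EMS) solution for the seven variance components of
# the random p x i x r design.

.COMPONENTS <- c("p", "i", "r", "pi", "pr", "ri", "pir_e")

#' Mean squares of the balanced crossed p x i x r design
#'
#' Classical balanced three-way ANOVA: sums of squares for the three main
#' effects, the three two-way interactions, and the residual (which, with
#' one observation per cell, is confounded with the three-way interaction),
#' each divided by its degrees of freedom. Computed directly from marginal
#' and cell means.
#'
#' Requires a balanced-complete table with at least two levels of each
#' facet. Unbalanced tables are refused: the EMS method implemented here is
#' exact only for balanced data (unbalanced designs call for likelihood
#' methods such as REML, outside this package's scope).
#'
#' @param scores A balanced [score_table].
#' @return A `gt_mean_squares` list: `ms` and `ss` (named vectors over
#'   `p, i, r, pi, pr, ri, pir_e`), `df` (degrees of freedom), `ss_total`,
#'   `grand_mean`, and the [gt_design].
#' @export
mean_squares <- function(scores) {
  design <- validate_balanced(scores)
  if (!design$balanced) {
    stop("score table is not balanced-complete; EMS estimation requires a ",
         "fully crossed design with one score per cell (for unbalanced data ",
         "use a REML-based mixed-model fit, not this function)", call. = FALSE)
  }
  if (design$n_p < 2 || design$n_i < 2 || design$n_r < 2) {
    stop("G-study estimation needs at least 2 persons, 2 items, and 2 raters",
         call. = FALSE)
  }
  n_p <- design$n_p; n_i <- design$n_i; n_r <- design$n_r
  x <- tapply(scores$score,
              list(factor(scores$person_id), factor(scores$item_id),
                   factor(scores$rater_id)),
              identity)
  m <- mean(x)
  m_p <- apply(x, 1, mean)
  m_i <- apply(x, 2, mean)
  m_r <- apply(x, 3, mean)
  m_pi <- apply(x, c(1, 2), mean)
  m_pr <- apply(x, c(1, 3), mean)
  m_ir <- apply(x, c(2, 3), mean)

  # two-way interaction deviation, e.g. m_pi - m_p - m_i + m
  dev2 <- function(mm, a, b) sweep(sweep(mm, 1, a), 2, b) + m
  ss <- c(
    p  = n_i * n_r * sum((m_p - m)^2),
    i  = n_p * n_r * sum((m_i - m)^2),
    r  = n_p * n_i * sum((m_r - m)^2),
    pi = n_r * sum(dev2(m_pi, m_p, m_i)^2),
    pr = n_i * sum(dev2(m_pr, m_p, m_r)^2),
    ri = n_p * sum(dev2(m_ir, m_i, m_r)^2),
    pir_e = NA_real_
  )
  dev3 <- x
  for (pp in seq_len(n_p)) for (ii in seq_len(n_i)) {
    dev3[pp, ii, ] <- x[pp, ii, ] - m_pi[pp, ii] - m_pr[pp, ] - m_ir[ii, ] +
      m_p[pp] + m_i[ii] + m_r - m
  }
  ss[["pir_e"]] <- sum(dev3^2)

  df <- c(p = n_p - 1, i = n_i - 1, r = n_r - 1,
          pi = (n_p - 1) * (n_i - 1), pr = (n_p - 1) * (n_r - 1),
          ri = (n_i - 1) * (n_r - 1),
          pir_e = (n_p - 1) * (n_i - 1) * (n_r - 1))
  structure(list(ms = ss / df, ss = ss, df = df,
                 ss_total = sum((x - m)^2), grand_mean = m, design = design),
            class = "gt_mean_squares")
}

#' @export
print.gt_mean_squares <- function(x, ...) {
  cat("Balanced p x i x r ANOVA mean squares\n")
  print(data.frame(effect = names(x$ms), df = unname(x$df),
                   SS = unname(x$ss), MS = unname(x$ms)), row.names = FALSE)
  invisible(x)
}

#' Construct a variance-components object
#'
#' Holds the seven variance components of the crossed p x i x r random
#' design: persons (the universe-score variance when persons are the object
#' of measurement), items, raters, the three two-way interactions, and the
#' residual confounded with the three-way interaction. Negative inputs
#' (which EMS estimation can produce) are kept in `$raw` and truncated to
#' zero in `$components`, the reported values.
#'
#' @param p,i,r,pi,pr,ri,pir_e The seven variances. Alternatively pass a
#'   single named vector as `p`.
#' @param label Optional label list or string (e.g. family and scoring
#'   system).
#' @return A `variance_components` object.
#' @export
variance_components <- function(p, i = NULL, r = NULL, pi = NULL, pr = NULL,
                                ri = NULL, pir_e = NULL, label = NULL) {
  if (length(p) == 7 && is.null(i)) {
    v <- as.numeric(p)
    if (!is.null(names(p))) {
      if (!setequal(names(p), .COMPONENTS)) {
        stop("component vector must be named ",
             paste(.COMPONENTS, collapse = ", "), call. = FALSE)
      }
      v <- as.numeric(p[.COMPONENTS])
    }
  } else {
    v <- c(p, i, r, pi, pr, ri, pir_e)
    if (length(v) != 7) stop("seven variance components required", call. = FALSE)
  }
  names(v) <- .COMPONENTS
  structure(list(components = pmax(v, 0), raw = v, label = label),
            class = "variance_components")
}

#' Estimate variance components by expected mean squares
#'
#' Solves the expected-mean-squares equations of the fully crossed two-facet
#' random model for the seven variance components:
#' \deqn{\hat\sigma^2(pir,e) = MS_{pir}}
#' \deqn{\hat\sigma^2(pi) = (MS_{pi} - MS_{pir}) / n_r}
#' \deqn{\hat\sigma^2(pr) = (MS_{pr} - MS_{pir}) / n_i}
#' \deqn{\hat\sigma^2(ir) = (MS_{ir} - MS_{pir}) / n_p}
#' \deqn{\hat\sigma^2(p) = (MS_p - MS_{pi} - MS_{pr} + MS_{pir}) / (n_i n_r)}
#' \deqn{\hat\sigma^2(i) = (MS_i - MS_{pi} - MS_{ir} + MS_{pir}) / (n_p n_r)}
#' \deqn{\hat\sigma^2(r) = (MS_r - MS_{pr} - MS_{ir} + MS_{pir}) / (n_p n_i)}
#'
#' Negative solutions (possible in small samples when a true component is
#' near zero) are reported raw and truncated to zero in the reported
#' components, the usual convention for tabulated G-study results.
#'
#' @param ms A `gt_mean_squares` from [mean_squares()].
#' @param design Optional [gt_design]; defaults to the one carried by `ms`.
#' @param label Passed to [variance_components()].
#' @return A [variance_components] object.
#' @export
estimate_variance_components <- function(ms, design = NULL, label = NULL) {
  stopifnot(inherits(ms, "gt_mean_squares"))
  if (is.null(design)) design <- ms$design
  n_p <- design$n_p; n_i <- design$n_i; n_r <- design$n_r
  if (n_p < 2 || n_i < 2 || n_r < 2) {
    stop("facets with fewer than 2 levels cannot be separated from their ",
         "interactions", call. = FALSE)
  }
  s <- ms$ms
  v <- c(
    p  = (s[["p"]] - s[["pi"]] - s[["pr"]] + s[["pir_e"]]) / (n_i * n_r),
    i  = (s[["i"]] - s[["pi"]] - s[["ri"]] + s[["pir_e"]]) / (n_p * n_r),
    r  = (s[["r"]] - s[["pr"]] - s[["ri"]] + s[["pir_e"]]) / (n_p * n_i),
    pi = (s[["pi"]] - s[["pir_e"]]) / n_r,
    pr = (s[["pr"]] - s[["pir_e"]]) / n_i,
    ri = (s[["ri"]] - s[["pir_e"]]) / n_p,
    pir_e = s[["pir_e"]]
  )
  variance_components(v, label = label)
}

#' Percent of total variance per component
#'
#' Each (truncated) component divided by the sum of all truncated
#' components, times 100. Returned at full precision; tabulated output
#' conventionally rounds to one decimal.
#'
#' @param vc A [variance_components] object or named 7-vector.
#' @return Named numeric vector of percentages summing to 100.
#' @export
percent_variance <- function(vc) {
  v <- if (inherits(vc, "variance_components")) vc$components else
    variance_components(vc)$components
  total <- sum(v)
  if (total <= 0) {
    stop("percent of variance is undefined when all components are zero",
         call. = FALSE)
  }
  100 * v / total
}

#' Run a full G-study on a balanced score table
#'
#' Convenience wrapper: [mean_squares()] then
#' [estimate_variance_components()].
#'
#' @param scores A balanced [score_table].
#' @param label Passed through to the result.
#' @return A [variance_components] object.
#' @export
gstudy <- function(scores, label = NULL) {
  estimate_variance_components(mean_squares(scores), label = label)
}

#' @export
print.variance_components <- function(x, ...) {
  if (!is.null(x$label)) {
    cat("G-study variance components [",
        paste(unlist(x$label), collapse = ", "), "]\n", sep = "")
  } else {
    cat("G-study variance components (crossed p x i x r random design)\n")
  }
  pct <- tryCatch(percent_variance(x), error = function(e) rep(NA_real_, 7))
  print(data.frame(source = c("p", "i", "r", "p x i", "p x r", "r x i",
                              "p x i x r, e"),
                   estimate = sprintf("%.3f", x$components),
                   percent = sprintf("%.1f", pct)), row.names = FALSE)
  invisible(x)
}

#' Format a G-study as a report table
#'
#' @param vc A [variance_components] object.
#' @return Data frame with columns `component`, `estimate` (3 decimals),
#'   `percent` (1 decimal), suitable for CSV export.
#' @export
gstudy_table <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  pct <- percent_variance(vc)
  data.frame(component = .COMPONENTS,
             estimate = round(vc$components, 3),
             percent = round(pct, 1),
             row.names = NULL)
}
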
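# D-study: projection of G-study variance components to candidate designs,
# error variances, generalizability / dependability coefficients, curves,
# and minimal-design search.

.get_components <- function(vc) {
  if (inherits(vc, "variance_components")) vc$components
  else variance_components(vc)$components
}

#' Round half away from zero
#'
#' Decimal rounding with ties going up (2.5 -> 3), the convention used in
#' reported reliability tables, rather than R's round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

.chk_design_n <- function(n_i, n_r) {
  if (!is.numeric(n_i) || !is.numeric(n_r) || n_i < 1 || n_r < 1 ||
      n_i != round(n_i) || n_r != round(n_r)) {
    stop("n_i and n_r must be positive integers", call. = FALSE)
  }
}

#' Relative error variance for a candidate design
#'
#' The error variance relevant to rank-order (relative) decisions: only the
#' components that interact with the person enter, each divided by the
#' number of conditions it is averaged over in the design:
#' \deqn{\sigma^2_\delta = \sigma^2(pi)/n_i + \sigma^2(pr)/n_r +
#'   \sigma^2(pir,e)/(n_i n_r)}
#'
#' @param vc A [variance_components] object or named 7-vector.
#' @param n_i,n_r Numbers of items and raters in the candidate design.
#' @return The relative error variance (a scalar).
#' @export
relative_error_variance <- function(vc, n_i, n_r) {
  .chk_design_n(n_i, n_r)
  v <- .get_components(vc)
  v[["pi"]] / n_i + v[["pr"]] / n_r + v[["pir_e"]] / (n_i * n_r)
}

#' Absolute error variance for a candidate design
#'
#' The error variance relevant to absolute (criterion-referenced) decisions:
#' every component except the person variance enters, so the facet main
#' effects count as error too:
#' \deqn{\sigma^2_\Delta = \sigma^2(i)/n_i + \sigma^2(r)/n_r +
#'   \sigma^2(pi)/n_i + \sigma^2(pr)/n_r +
#'   \sigma^2(ir)/(n_i n_r) + \sigma^2(pir,e)/(n_i n_r)}
#'
#' Always at least as large as the relative error variance.
#'
#' @inheritParams relative_error_variance
#' @return The absolute error variance (a scalar).
#' @export
absolute_error_variance <- function(vc, n_i, n_r) {
  .chk_design_n(n_i, n_r)
  v <- .get_components(vc)
  v[["i"]] / n_i + v[["r"]] / n_r + v[["pi"]] / n_i + v[["pr"]] / n_r +
    v[["ri"]] / (n_i * n_r) + v[["pir_e"]] / (n_i * n_r)
}

#' Generalizability coefficient
#'
#' The ratio of universe-score variance to itself plus relative error
#' variance, \eqn{E\rho^2 = \sigma^2_\tau / (\sigma^2_\tau +
#' \sigma^2_\delta)}, with the person variance as the universe-score
#' variance. Interpreted on the same scale as coefficient alpha; 0.80 or
#' better is conventionally excellent.
#'
#' @param sigma2_p Universe-score (person) variance, >= 0.
#' @param sigma2_delta Relative error variance, >= 0; not both zero.
#' @return The coefficient, in \[0, 1\].
#' @export
generalizability_coefficient <- function(sigma2_p, sigma2_delta) {
  stopifnot(sigma2_p >= 0, sigma2_delta >= 0)
  if (sigma2_p == 0 && sigma2_delta == 0) {
    stop("generalizability coefficient undefined: no variance at all",
         call. = FALSE)
  }
  sigma2_p / (sigma2_p + sigma2_delta)
}

#' Dependability coefficient
#'
#' As [generalizability_coefficient()] but with absolute error variance in
#' the denominator: \eqn{\Phi = \sigma^2_\tau / (\sigma^2_\tau +
#' \sigma^2_\Delta)}. Because absolute error includes the facet main
#' effects, \eqn{\Phi \le E\rho^2} always.
#'
#' @param sigma2_p Universe-score (person) variance, >= 0.
#' @param sigma2_Delta Absolute error variance, >= 0; not both zero.
#' @return The coefficient, in \[0, 1\].
#' @export
dependability_coefficient <- function(sigma2_p, sigma2_Delta) {
  stopifnot(sigma2_p >= 0, sigma2_Delta >= 0)
  if (sigma2_p == 0 && sigma2_Delta == 0) {
    stop("dependability coefficient undefined: no variance at all",
         call. = FALSE)
  }
  sigma2_p / (sigma2_p + sigma2_Delta)
}

#' Full D-study for one candidate design
#'
#' Projects each G-study component to the candidate design (person variance
#' unchanged; item-linked components divided by `n_i`, rater-linked by
#' `n_r`, and components involving both facets by `n_i * n_r`), then forms
#' both error variances and both coefficients.
#'
#' With `printed = TRUE` the projected components are first rounded to
#' three decimals and the error variances and coefficients are formed from
#' the rounded values — the convention of published D-study tables, where
#' the printed error variance equals the sum of the printed components.
#' Full precision (`printed = FALSE`) is the default for analysis.
#'
#' @inheritParams relative_error_variance
#' @param printed Reproduce printed-table arithmetic (see Details).
#' @return A `dstudy_result` list: `n_i`, `n_r`, `projected` (named
#'   7-vector), `sigma2_delta`, `sigma2_Delta`, `e_rho2`, `phi`.
#' @export
dstudy_table <- function(vc, n_i, n_r, printed = FALSE) {
  .chk_design_n(n_i, n_r)
  v <- .get_components(vc)
  divisors <- c(p = 1, i = n_i, r = n_r, pi = n_i, pr = n_r,
                ri = n_i * n_r, pir_e = n_i * n_r)
  proj <- v / divisors[names(v)]
  if (printed) proj <- round_half_up(proj, 3)
  s_delta <- proj[["pi"]] + proj[["pr"]] + proj[["pir_e"]]
  s_Delta <- s_delta + proj[["i"]] + proj[["r"]] + proj[["ri"]]
  structure(list(
    n_i = as.integer(n_i), n_r = as.integer(n_r),
    projected = proj,
    sigma2_delta = s_delta,
    sigma2_Delta = s_Delta,
    e_rho2 = generalizability_coefficient(proj[["p"]], s_delta),
    phi = dependability_coefficient(proj[["p"]], s_Delta),
    printed = printed,
    label = if (inherits(vc, "variance_components")) vc$label else NULL
  ), class = "dstudy_result")
}

#' @export
print.dstudy_result <- function(x, ...) {
  cat(sprintf("D-study for %d item(s) x %d rater(s)%s\n", x$n_i, x$n_r,
              if (x$printed) " [printed-table arithmetic]" else ""))
  df <- format_dstudy(x)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Format a D-study result as a report table
#'
#' Rows mirror the conventional published layout: the seven projected
#' components (3 decimals) with their design divisors, then the two error
#' variances (3 decimals) and the two coefficients, rounded half-up to two
#' decimals.
#'
#' @param x A `dstudy_result` from [dstudy_table()].
#' @return Data frame with columns `quantity`, `n`, `estimate`.
#' @export
format_dstudy <- function(x) {
  stopifnot(inherits(x, "dstudy_result"))
  divisors <- c(1, x$n_i, x$n_r, x$n_i, x$n_r, x$n_i * x$n_r, x$n_i * x$n_r)
  data.frame(
    quantity = c("sigma2_p", "sigma2_i", "sigma2_r", "sigma2_pi", "sigma2_pr",
                 "sigma2_ri", "sigma2_pir_e", "sigma2_delta", "sigma2_Delta",
                 "e_rho2", "phi"),
    n = c(divisors, NA, NA, NA, NA),
    estimate = c(round_half_up(unname(x$projected), 3),
                 round_half_up(c(x$sigma2_delta, x$sigma2_Delta), 3),
                 round_half_up(c(x$e_rho2, x$phi), 2)),
    row.names = NULL)
}

#' Coefficient as one facet's size varies
#'
#' Evaluates the generalizability or dependability coefficient for designs
#' with `n = 1..max_n` levels of one facet, holding the other facet fixed —
#' the data behind the reliability-projection curves used to choose how many
#' raters or items a study needs. Both coefficients are nondecreasing in
#' either facet size.
#'
#' @inheritParams relative_error_variance
#' @param varying `"raters"` or `"items"`: the facet whose size varies.
#' @param fixed_n Size of the other facet.
#' @param max_n Largest size evaluated (curve runs over 1..max_n).
#' @param which `"e_rho2"` or `"phi"`.
#' @return A `coefficient_curve` data frame with columns `n` and
#'   `coefficient`; attributes record the varying facet, the fixed size and
#'   the statistic.
#' @export
coefficient_curve <- function(vc, varying = c("raters", "items"),
                              fixed_n = 2, max_n = 10,
                              which = c("e_rho2", "phi")) {
  varying <- match.arg(varying)
  which <- match.arg(which)
  stopifnot(max_n >= 1, fixed_n >= 1)
  vals <- vapply(seq_len(max_n), function(n) {
    n_i <- if (varying == "items") n else fixed_n
    n_r <- if (varying == "raters") n else fixed_n
    d <- dstudy_table(vc, n_i, n_r)
    if (which == "e_rho2") d$e_rho2 else d$phi
  }, numeric(1))
  out <- data.frame(n = seq_len(max_n), coefficient = vals)
  attr(out, "varying") <- varying
  attr(out, "fixed_n") <- as.integer(fixed_n)
  attr(out, "which") <- which
  class(out) <- c("coefficient_curve", "data.frame")
  out
}

#' Smallest design reaching a target coefficient
#'
#' Searches `n = 1..cap` levels of one facet (the other held fixed) for the
#' smallest design whose coefficient meets or exceeds `threshold`.
#' Integer designs only; no interpolation.
#'
#' @inheritParams coefficient_curve
#' @param threshold Target coefficient, strictly between 0 and 1
#'   (0.80 is the conventional bar for "excellent").
#' @param cap Largest facet size considered.
#' @return The smallest qualifying `n`, or `NA_integer_` if none up to
#'   `cap` qualifies.
#' @export
minimal_design <- function(vc, threshold = 0.80,
                           varying = c("raters", "items"), fixed_n = 2,
                           which = c("e_rho2", "phi"), cap = 10) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1) {
    stop("threshold must be strictly between 0 and 1", call. = FALSE)
  }
  curve <- coefficient_curve(vc, varying = varying, fixed_n = fixed_n,
                             max_n = cap, which = which)
  hit <- which(curve$coefficient >= threshold)
  if (length(hit) == 0) NA_integer_ else as.integer(curve$n[hit[1]])
}
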
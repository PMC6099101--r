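# Published reference variance components for divergent-thinking ratings,
# used in worked examples and as generating truth in simulation studies.

#' Reference G-study variance components for divergent-thinking ratings
#'
#' Variance components reported by a published crossed p x i x r G-study of
#' divergent-thinking creativity ratings (80 persons, 2 items per task
#' family, 3 crowdsourced raters, 1-5 scale), for two scoring systems:
#' the average-rating system (every response rated, then averaged per
#' rater and item) and the snapshot system (one holistic rating per
#' person-item-rater). Estimates are as printed, to three decimals, one
#' column per task family.
#'
#' For the average-rating system the person variance carried forward to the
#' published D-study stage differs in the last decimal for the consequences
#' family (0.068 vs. 0.067, a rounding artifact of the source tables);
#' `stage = "dstudy"` returns that variant so that worked D-study examples
#' reproduce the published coefficients exactly.
#'
#' @param system `"average"` or `"snapshot"`.
#' @param family `"alternative_uses"` or `"consequences"`.
#' @param stage `"gstudy"` (default) or `"dstudy"` (see Details).
#' @return A [variance_components] object.
#' @export
#' @examples
#' vc <- reference_components("average", "alternative_uses")
#' dstudy_table(vc, n_i = 2, n_r = 3, printed = TRUE)
reference_components <- function(system = c("average", "snapshot"),
                                 family = c("alternative_uses", "consequences"),
                                 stage = c("gstudy", "dstudy")) {
  system <- match.arg(system)
  family <- match.arg(family)
  stage <- match.arg(stage)
  tab <- list(
    average = list(
      alternative_uses = c(p = 0.167, i = 0.069, r = 0.181, pi = 0.139,
                           pr = 0.008, ri = 0.021, pir_e = 0.096),
      consequences     = c(p = 0.067, i = 0.000, r = 0.351, pi = 0.088,
                           pr = 0.015, ri = 0.008, pir_e = 0.088)
    ),
    snapshot = list(
      alternative_uses = c(p = 0.098, i = 0.041, r = 0.286, pi = 0.000,
                           pr = 0.104, ri = 0.027, pir_e = 0.971),
      consequences     = c(p = 0.100, i = 0.016, r = 0.161, pi = 0.034,
                           pr = 0.026, ri = 0.000, pir_e = 1.065)
    )
  )
  v <- tab[[system]][[family]]
  if (stage == "dstudy" && system == "average" && family == "consequences") {
    v[["p"]] <- 0.068
  }
  variance_components(v, label = list(system = system, family = family))
}
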
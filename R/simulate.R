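# Synthetic rating data from the additive crossed random-effects model, at
# score level and response level, plus a Monte-Carlo parameter-recovery
# harness.

#' Specification for a synthetic rating study
#'
#' Collects everything the generator needs: the seven true variance
#' components of the crossed p x i x r model, the grand mean of the rating
#' scale, the design sizes, and a seed. Defaults mirror the study design the
#' package is built around: 80 persons, 2 items within one task family,
#' 3 raters, a scale centered at 3, and per-item fluency averaging 6.5
#' responses; the default true components are the published average-rating
#' alternative-uses estimates (see [reference_components()]).
#'
#' @param true_components A [variance_components] object or named 7-vector
#'   of non-negative true variances.
#' @param grand_mean Center of the rating scale (default 3, the midpoint of
#'   1-5).
#' @param n_p,n_i,n_r Design sizes (persons, items, raters).
#' @param seed Integer seed; a fixed seed makes the output bit-identical
#'   across runs.
#' @param discretize Clip to \[1, 5\] and round scores to the integer scale.
#'   Off by default: the estimation theory is moment-based and continuous
#'   scores keep component recovery unbiased; discretization is offered to
#'   emulate raw integer ratings, at a documented cost of downward bias.
#' @param fluency_mean Mean of the zero-truncated Poisson number of
#'   responses per (person, item); response-level mode only.
#' @param response_sd SD of the within-cell response/rater rating noise
#'   around the cell expectation; response-level mode only.
#' @param family Task family label given to the simulated items.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(true_components = reference_components(),
                            grand_mean = 3, n_p = 80, n_i = 2, n_r = 3,
                            seed = 1L, discretize = FALSE,
                            fluency_mean = 6.5, response_sd = 0.5,
                            family = "alternative_uses") {
  v <- if (inherits(true_components, "variance_components"))
    true_components$components else variance_components(true_components)$components
  stopifnot(all(v >= 0), n_p >= 1, n_i >= 1, n_r >= 1, fluency_mean > 0,
            response_sd >= 0)
  .chk_family(family)
  structure(list(true_components = v, grand_mean = grand_mean,
                 n_p = as.integer(n_p), n_i = as.integer(n_i),
                 n_r = as.integer(n_r), seed = as.integer(seed),
                 discretize = isTRUE(discretize),
                 fluency_mean = fluency_mean, response_sd = response_sd,
                 family = family),
            class = "simulation_spec")
}

.sim_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

# family-specific item ids so tables from different families can be stacked
.sim_item_ids <- function(family, n) {
  prefix <- c(alternative_uses = "au_i", consequences = "co_i")[[family]]
  sprintf("%s%02d", prefix, seq_len(n))
}

# Draw the additive crossed effects and return the n_p x n_i x n_r array of
# cell expectations mu + nu_p + nu_i + nu_r + nu_pi + nu_pr + nu_ir (+ e if
# with_residual).
.sim_cell_means <- function(spec, with_residual = TRUE) {
  v <- spec$true_components
  n_p <- spec$n_p; n_i <- spec$n_i; n_r <- spec$n_r
  e_p <- stats::rnorm(n_p, 0, sqrt(v[["p"]]))
  e_i <- stats::rnorm(n_i, 0, sqrt(v[["i"]]))
  e_r <- stats::rnorm(n_r, 0, sqrt(v[["r"]]))
  e_pi <- matrix(stats::rnorm(n_p * n_i, 0, sqrt(v[["pi"]])), n_p, n_i)
  e_pr <- matrix(stats::rnorm(n_p * n_r, 0, sqrt(v[["pr"]])), n_p, n_r)
  e_ir <- matrix(stats::rnorm(n_i * n_r, 0, sqrt(v[["ri"]])), n_i, n_r)
  x <- array(spec$grand_mean, dim = c(n_p, n_i, n_r))
  x <- x + outer(outer(e_p, e_i, `+`), e_r, `+`)
  for (rr in seq_len(n_r)) {
    x[, , rr] <- x[, , rr] + e_pi +
      matrix(e_pr[, rr], n_p, n_i) +
      matrix(e_ir[, rr], n_p, n_i, byrow = TRUE)
  }
  if (with_residual) {
    x <- x + array(stats::rnorm(n_p * n_i * n_r, 0, sqrt(v[["pir_e"]])),
                   dim = dim(x))
  }
  x
}

#' Simulate score-level rating data
#'
#' Draws one score per (person, item, rater) cell from the additive crossed
#' random-effects model \eqn{X_{pir} = \mu + \nu_p + \nu_i + \nu_r +
#' \nu_{pi} + \nu_{pr} + \nu_{ir} + \epsilon_{pir}}, each effect independent
#' zero-mean normal with its specified variance — exactly the model whose
#' seven components the G-study estimates. With `discretize = TRUE` scores
#' are clipped to \[1, 5\] and rounded to integers (this biases component
#' recovery toward zero and is off by default).
#'
#' @param spec A [simulation_spec].
#' @return A balanced [score_table] covering the full
#'   `n_p x n_i x n_r` grid.
#' @export
simulate_scores <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  x <- .sim_cell_means(spec, with_residual = TRUE)
  if (spec$discretize) x <- pmin(5, pmax(1, round(x)))
  grid <- expand.grid(person_id = .sim_ids("p", spec$n_p),
                      item_id = .sim_item_ids(spec$family, spec$n_i),
                      rater_id = .sim_ids("r", spec$n_r),
                      stringsAsFactors = FALSE)
  grid$family <- spec$family
  grid$score <- as.vector(x)
  grid <- grid[order(grid$person_id, grid$item_id, grid$rater_id), ]
  out <- grid[, c("person_id", "family", "item_id", "rater_id", "score")]
  rownames(out) <- NULL
  class(out) <- c("score_table", "data.frame")
  out
}

#' Simulate response-level rating data
#'
#' Emulates the structure of a response-level divergent-thinking rating
#' study: each (person, item) pair gets a zero-truncated-Poisson number of
#' responses (mean `fluency_mean`), and every response is rated by every
#' rater with an integer 1-5 rating whose cell expectation follows the
#' score-level model of [simulate_scores()]. Each rating is the cell
#' expectation plus independent normal noise (`response_sd`), rounded and
#' clipped to the integer scale.
#'
#' @param spec A [simulation_spec].
#' @return A [response_ratings] table.
#' @export
simulate_response_level <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  mu <- .sim_cell_means(spec, with_residual = TRUE)
  persons <- .sim_ids("p", spec$n_p)
  items <- .sim_item_ids(spec$family, spec$n_i)
  raters <- .sim_ids("r", spec$n_r)
  fl <- matrix(.rztpois(spec$n_p * spec$n_i, spec$fluency_mean),
               spec$n_p, spec$n_i)
  rows <- vector("list", spec$n_p * spec$n_i)
  k <- 0
  for (pp in seq_len(spec$n_p)) for (ii in seq_len(spec$n_i)) {
    n_resp <- fl[pp, ii]
    resp_ids <- sprintf("%s_%s_resp%02d", persons[pp], items[ii],
                        seq_len(n_resp))
    noise <- matrix(stats::rnorm(n_resp * spec$n_r, 0, spec$response_sd),
                    n_resp, spec$n_r)
    rating <- pmin(5, pmax(1, round(
      matrix(mu[pp, ii, ], n_resp, spec$n_r, byrow = TRUE) + noise)))
    k <- k + 1
    rows[[k]] <- data.frame(
      person_id = persons[pp], family = spec$family, item_id = items[ii],
      rater_id = rep(raters, each = n_resp),
      response_id = rep(resp_ids, times = spec$n_r),
      rating = as.vector(rating), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  response_ratings(out)
}

# Zero-truncated Poisson with a given mean: solve for the underlying rate
# (mean of ZTP at rate l is l / (1 - exp(-l))), then sample by inverse CDF
# conditional on being positive.
.rztpois <- function(n, mean) {
  stopifnot(mean > 1)
  lambda <- stats::uniroot(function(l) l / (1 - exp(-l)) - mean,
                           lower = 1e-8, upper = mean + 10)$root
  u <- stats::runif(n, stats::ppois(0, lambda), 1)
  stats::qpois(u, lambda)
}

#' Monte-Carlo parameter recovery of the G-study estimator
#'
#' Repeatedly simulates score tables from a known truth and re-estimates
#' the seven components, summarizing the sampling distribution of the raw
#' (untruncated) EMS estimates: per-component mean estimate, bias,
#' replicate SD, and Monte-Carlo standard error of the mean. Per-replicate
#' seeds are derived deterministically from the spec's seed.
#'
#' @param spec A [simulation_spec] giving the truth and design.
#' @param n_reps Number of replicates (>= 2).
#' @return A `recovery_summary` data frame: `component`, `truth`,
#'   `mean_estimate`, `bias`, `sd`, `se`; the matrix of per-replicate
#'   estimates is attached as attribute `"estimates"`.
#' @export
parameter_recovery <- function(spec, n_reps = 200) {
  stopifnot(inherits(spec, "simulation_spec"), n_reps >= 2)
  set.seed(spec$seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  est <- matrix(NA_real_, n_reps, 7,
                dimnames = list(NULL, names(spec$true_components)))
  for (k in seq_len(n_reps)) {
    rspec <- spec
    rspec$seed <- rep_seeds[k]
    vc <- gstudy(simulate_scores(rspec))
    est[k, ] <- vc$raw
  }
  mean_est <- colMeans(est)
  sd_est <- apply(est, 2, stats::sd)
  out <- data.frame(component = colnames(est),
                    truth = unname(spec$true_components),
                    mean_estimate = unname(mean_est),
                    bias = unname(mean_est - spec$true_components),
                    sd = unname(sd_est),
                    se = unname(sd_est / sqrt(n_reps)),
                    row.names = NULL)
  attr(out, "estimates") <- est
  class(out) <- c("recovery_summary", "data.frame")
  out
}
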
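# Shared fixtures and independent oracles.

# Write a data frame to a temp CSV, return the path.
write_temp_csv <- function(df) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Response-level fixture: 2 persons x 1 item x 2 raters x 2 responses.
response_fixture_8 <- function() {
  expand.grid(person_id = c("p1", "p2"), item_id = "brick",
              rater_id = c("rA", "rB"), response_id = c("s1", "s2"),
              stringsAsFactors = FALSE) |>
    transform(family = "alternative_uses",
              rating = c(1, 2, 3, 4, 5, 1, 2, 3))
}

# Full p x i x r score grid with the given score vector (filled in
# person-fastest order).
grid_scores <- function(n_p, n_i, n_r, scores,
                        family = "alternative_uses") {
  g <- expand.grid(person_id = sprintf("p%02d", seq_len(n_p)),
                   item_id = sprintf("i%02d", seq_len(n_i)),
                   rater_id = sprintf("r%02d", seq_len(n_r)),
                   stringsAsFactors = FALSE)
  g$family <- family
  g$score <- scores
  if (all(scores >= 1 & scores <= 5)) return(score_table(g))
  # off-scale synthetic values: bypass the loader's scale-bounds check
  out <- g[, c("person_id", "family", "item_id", "rater_id", "score")]
  class(out) <- c("score_table", "data.frame")
  out
}

random_grid <- function(n_p, n_i, n_r, lo = 1, hi = 5) {
  grid_scores(n_p, n_i, n_r,
              stats::runif(n_p * n_i * n_r, lo, hi))
}

# Independent sums-of-squares oracle: base R ANOVA on crossed factors.
aov_ss_oracle <- function(scores) {
  df <- as.data.frame(scores)
  df$p <- factor(df$person_id)
  df$i <- factor(df$item_id)
  df$r <- factor(df$rater_id)
  # the saturated fit has 0 residual df; its F-test warning is irrelevant
  # to the sums of squares we extract
  tab <- suppressWarnings(stats::anova(stats::lm(score ~ p * i * r,
                                                 data = df)))
  ss <- tab$`Sum Sq`
  names(ss) <- rownames(tab)
  c(p = ss[["p"]], i = ss[["i"]], r = ss[["r"]],
    pi = ss[["p:i"]], pr = ss[["p:r"]], ri = ss[["i:r"]],
    pir_e = ss[["p:i:r"]])
}

# Independent EMS oracle: solve the 7x7 expected-mean-squares linear system
# numerically instead of using the closed form.
ems_solve_oracle <- function(ms_obj) {
  d <- ms_obj$design
  np <- d$n_p; ni <- d$n_i; nr <- d$n_r
  # rows: E[MS_p], E[MS_i], E[MS_r], E[MS_pi], E[MS_pr], E[MS_ir], E[MS_pir]
  # cols: sigma2 p, i, r, pi, pr, ri, pir_e
  A <- rbind(
    c(ni * nr, 0, 0, nr, ni, 0, 1),
    c(0, np * nr, 0, nr, 0, np, 1),
    c(0, 0, np * ni, 0, ni, np, 1),
    c(0, 0, 0, nr, 0, 0, 1),
    c(0, 0, 0, 0, ni, 0, 1),
    c(0, 0, 0, 0, 0, np, 1),
    c(0, 0, 0, 0, 0, 0, 1))
  v <- solve(A, unname(ms_obj$ms[c("p", "i", "r", "pi", "pr", "ri",
                                   "pir_e")]))
  names(v) <- c("p", "i", "r", "pi", "pr", "ri", "pir_e")
  v
}

# Random non-negative variance-component set on a realistic scale.
random_components <- function() {
  variance_components(stats::setNames(stats::runif(7, 0, 0.5),
                                      c("p", "i", "r", "pi", "pr", "ri",
                                        "pir_e")))
}
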
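test_that("average-rating scores are per-rater means over a person's responses", {
  one <- response_ratings(data.frame(
    person_id = "p1", family = "alternative_uses", item_id = "brick",
    rater_id = "rA", response_id = "s1", rating = 4))
  expect_equal(average_rating_scores(one)$score, 4.0)

  three <- response_ratings(data.frame(
    person_id = "p1", family = "alternative_uses", item_id = "brick",
    rater_id = "rA", response_id = c("s1", "s2", "s3"),
    rating = c(1, 3, 5)))
  expect_equal(average_rating_scores(three)$score, 3.0)

  # 2 persons x 1 item x 2 raters x 2 responses, hand-computed cell means
  fix <- response_ratings(response_fixture_8())
  st <- average_rating_scores(fix)
  got <- stats::setNames(st$score, paste(st$person_id, st$rater_id))
  by_hand <- c("p1 rA" = mean(c(1, 5)), "p2 rA" = mean(c(2, 1)),
               "p1 rB" = mean(c(3, 2)), "p2 rB" = mean(c(4, 3)))
  expect_equal(got[names(by_hand)], by_hand)
})

test_that("average-rating scores: permutation invariance and bounds", {
  set.seed(42)
  for (rep in 1:5) {
    n_resp <- sample(2:6, 1)
    resp <- expand.grid(person_id = c("p1", "p2"), item_id = "knife",
                        rater_id = c("rA", "rB", "rC"),
                        response_id = sprintf("s%d", seq_len(n_resp)),
                        stringsAsFactors = FALSE)
    resp$family <- "alternative_uses"
    resp$rating <- sample(1:5, nrow(resp), replace = TRUE)
    st1 <- average_rating_scores(response_ratings(resp))
    st2 <- average_rating_scores(response_ratings(resp[sample(nrow(resp)), ]))
    expect_equal(as.data.frame(st1), as.data.frame(st2))
    expect_true(all(st1$score >= min(resp$rating) &
                      st1$score <= max(resp$rating)))
  }
})

test_that("a person-item pair rated by only some raters is refused", {
  resp <- response_fixture_8()
  broken <- resp[!(resp$person_id == "p2" & resp$rater_id == "rB"), ]
  expect_error(average_rating_scores(response_ratings(broken)),
               "incomplete cells")
})

test_that("snapshot scoring is pass-through validation", {
  st <- simulate_scores(simulation_spec(seed = 5, discretize = TRUE))
  expect_identical(snapshot_scores(st), st)
  dup <- rbind(as.data.frame(st), as.data.frame(st[1, ]))
  expect_error(snapshot_scores(score_table(dup)), "one rating per")
})

test_that("fluency counts responses per prompt, zero-filling the grid", {
  resp <- response_ratings(data.frame(
    person_id = c(rep("p1", 4), rep("p1", 2), rep("p2", 1)),
    family = "alternative_uses",
    item_id = c(rep("brick", 4), rep("knife", 2), "brick"),
    rater_id = "rA",
    response_id = c(sprintf("b%d", 1:4), sprintf("k%d", 1:2), "b1"),
    rating = 3))
  fl <- fluency_scores(resp)
  key <- stats::setNames(fl$fluency, paste(fl$person_id, fl$item_id))
  expect_equal(key[["p1 brick"]], 4L)
  expect_equal(key[["p1 knife"]], 2L)
  expect_equal(key[["p2 brick"]], 1L)
  expect_equal(key[["p2 knife"]], 0L)  # absent pair counts zero

  # a response rated by every rater still counts once
  multi <- response_ratings(data.frame(
    person_id = "p1", family = "alternative_uses", item_id = "brick",
    rater_id = c("rA", "rB", "rC"), response_id = "s1", rating = 3))
  expect_equal(fluency_scores(multi)$fluency, 1L)
})

test_that("composites: per-item rater means and per-family means of means", {
  st <- score_table(data.frame(
    person_id = "p1", family = "alternative_uses", item_id = "brick",
    rater_id = c("rA", "rB", "rC"), score = c(2, 3, 4)))
  ci <- composite_scores(st, level = "per_item")
  expect_equal(ci$value, 3.0)
  expect_equal(ci$variable_name, "average_brick")

  st2 <- score_table(data.frame(
    person_id = "p1", family = "alternative_uses",
    item_id = rep(c("brick", "knife"), each = 2),
    rater_id = rep(c("rA", "rB"), 2), score = c(2, 2, 4, 4)))
  cf <- composite_scores(st2, level = "per_family")
  expect_equal(cf$value, 3.0)
  expect_equal(cf$variable_name, "average_alternative_uses")
})

test_that("per-family composites equal per-item composites averaged over items", {
  st <- simulate_scores(simulation_spec(n_p = 80, n_i = 2, n_r = 3, seed = 9))
  per_item <- composite_scores(st, level = "per_item")
  per_fam <- composite_scores(st, level = "per_family")
  # independent group-by mean oracle
  oracle <- tapply(per_item$value, per_item$person_id, mean)
  got <- stats::setNames(per_fam$value, per_fam$person_id)
  expect_equal(unname(got[names(oracle)]), as.vector(oracle),
               tolerance = 1e-12)

  # and per-item equals brute-force mean over raters
  df <- as.data.frame(st)
  key <- paste(df$person_id, df$item_id)
  cell_oracle <- tapply(df$score, key, mean)
  got_items <- stats::setNames(
    per_item$value, paste(per_item$person_id,
                          sub("^average_", "", per_item$variable_name)))
  expect_equal(unname(got_items[names(cell_oracle)]),
               as.vector(cell_oracle), tolerance = 1e-12)
})
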
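test_that("response-level CSVs load with family derived from an item map", {
  path <- write_temp_csv(data.frame(
    person_id = "p1", item_id = "brick", rater_id = "raterA",
    response_id = "resp1", rating = 3))
  tab <- load_ratings(path, "response_level",
                      item_map = c(brick = "alternative_uses"))
  expect_s3_class(tab, "response_ratings")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$rating, 3)
  expect_equal(tab$family, "alternative_uses")

  eight <- response_fixture_8()
  tab8 <- load_ratings(write_temp_csv(eight), "response_level",
                       item_map = c(brick = "alternative_uses"))
  expect_equal(nrow(tab8), 8L)
  expect_equal(length(unique(tab8$person_id)), 2L)
  expect_equal(length(unique(tab8$rater_id)), 2L)
})

test_that("schema and validation errors are specific", {
  bad_bounds <- data.frame(person_id = "p1", family = "alternative_uses",
                           item_id = "brick", rater_id = "rA",
                           response_id = "s1", rating = 6)
  expect_error(load_ratings(write_temp_csv(bad_bounds), "response_level"),
               "\\[1, 5\\]")
  no_col <- bad_bounds[, setdiff(names(bad_bounds), "rater_id")]
  expect_error(load_ratings(write_temp_csv(no_col), "response_level"),
               "rater_id")
  non_num <- transform(bad_bounds, rating = "high")
  expect_error(load_ratings(write_temp_csv(non_num), "response_level"),
               "non-numeric")
  dup <- rbind(transform(bad_bounds, rating = 3),
               transform(bad_bounds, rating = 4))
  expect_error(load_ratings(write_temp_csv(dup), "response_level"),
               "duplicate")
  two_fams <- data.frame(person_id = c("p1", "p2"),
                         family = c("alternative_uses", "consequences"),
                         item_id = "brick", rater_id = "rA",
                         response_id = c("s1", "s2"), rating = 3)
  expect_error(response_ratings(two_fams), "more than one family")
})

test_that("write then load round-trips a score table exactly", {
  st <- grid_scores(3, 2, 2, seq(1, 5, length.out = 12))
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings(st, path)
  back <- load_ratings(path, "score_level")
  expect_equal(as.data.frame(back), as.data.frame(st))
})

test_that("validate_balanced detects completeness, holes, and duplicates", {
  full <- grid_scores(2, 2, 2, rep(3, 8))
  d <- validate_balanced(full)
  expect_equal(unclass(d)[c("n_p", "n_i", "n_r")],
               list(n_p = 2L, n_i = 2L, n_r = 2L))
  expect_true(d$balanced)

  hole <- full[-5, ]
  class(hole) <- class(full)
  expect_false(validate_balanced(hole)$balanced)

  dup <- rbind(as.data.frame(full), as.data.frame(full[1, ]))
  class(dup) <- class(full)
  expect_error(validate_balanced(dup), "duplicated")
})

test_that("validate_balanced is invariant to row order and accepts generator output", {
  st <- simulate_scores(simulation_spec(n_p = 80, n_i = 2, n_r = 3, seed = 11))
  d <- validate_balanced(st)
  expect_true(d$balanced)
  expect_equal(c(d$n_p, d$n_i, d$n_r), c(80L, 2L, 3L))

  shuffled <- st[sample(nrow(st)), ]
  class(shuffled) <- class(st)
  d2 <- validate_balanced(shuffled)
  expect_equal(unclass(d), unclass(d2))
})

test_that("item maps load from YAML and CSV configs", {
  ymap <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("brick: alternative_uses", "sleep: consequences"), ymap)
  m <- read_item_map(ymap)
  expect_equal(m[["sleep"]], "consequences")
  cmap <- write_temp_csv(data.frame(item_id = c("brick", "sleep"),
                                    family = c("alternative_uses",
                                               "consequences")))
  expect_equal(read_item_map(cmap), m)
  bad <- write_temp_csv(data.frame(item_id = "x", family = "poetry"))
  expect_error(read_item_map(bad), "unknown task family")
})
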
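au <- reference_components("average", "alternative_uses")
cons_d <- reference_components("average", "consequences", stage = "dstudy")
snap_au <- reference_components("snapshot", "alternative_uses")

test_that("relative error variance follows its defining sum", {
  vc <- variance_components(c(p = 1, i = 1, r = 1, pi = 0.6, pr = 0.3,
                              ri = 1, pir_e = 0.6))
  expect_equal(relative_error_variance(vc, 2, 3), 0.3 + 0.1 + 0.1)
  zero <- variance_components(c(p = 1, i = 1, r = 1, pi = 0, pr = 0,
                                ri = 1, pir_e = 0))
  expect_equal(relative_error_variance(zero, 4, 4), 0)
  expect_error(relative_error_variance(vc, -1, 3), "positive integers")
})

test_that("absolute minus relative error equals the facet main-effect share", {
  set.seed(7)
  for (k in 1:20) {
    vc <- random_components()
    n_i <- sample(1:10, 1); n_r <- sample(1:10, 1)
    gap <- absolute_error_variance(vc, n_i, n_r) -
      relative_error_variance(vc, n_i, n_r)
    v <- vc$components
    expect_equal(gap, v[["i"]] / n_i + v[["r"]] / n_r +
                   v[["ri"]] / (n_i * n_r), tolerance = 1e-12)
  }
})

test_that("coefficients reproduce the published 3-rater, 2-item worked examples", {
  # average ratings, both families
  expect_equal(round_half_up(generalizability_coefficient(0.167, 0.088), 2),
               0.65)
  expect_equal(round_half_up(dependability_coefficient(0.167, 0.187), 2),
               0.47)
  expect_equal(round_half_up(dependability_coefficient(0.068, 0.182), 2),
               0.27)
  # snapshot, from printed components: 0.098 / (0.098 + 0.196)
  expect_equal(round_half_up(generalizability_coefficient(0.098, 0.196), 2),
               0.33)
  # degenerate cases
  expect_equal(generalizability_coefficient(0.4, 0), 1.0)
  expect_equal(dependability_coefficient(0.4, 0), 1.0)
  expect_error(generalizability_coefficient(0, 0), "undefined")
})

test_that("dstudy_table projects components by their design divisors", {
  d <- dstudy_table(au, 2, 3)
  v <- au$components
  expect_equal(unname(d$projected),
               unname(v / c(1, 2, 3, 2, 3, 6, 6)), tolerance = 1e-12)
  expect_equal(d$sigma2_delta,
               v[["pi"]] / 2 + v[["pr"]] / 3 + v[["pir_e"]] / 6)
  # unit design leaves components unprojected
  d11 <- dstudy_table(au, 1, 1)
  expect_equal(d11$projected, v)
  expect_equal(d11$e_rho2,
               v[["p"]] / (v[["p"]] + v[["pi"]] + v[["pr"]] + v[["pir_e"]]))

  # snapshot AU relative error at (2, 3): 0/2 + 0.104/3 + 0.971/6
  d_snap <- dstudy_table(snap_au, 2, 3)
  expect_equal(d_snap$sigma2_delta, 0.104 / 3 + 0.971 / 6, tolerance = 1e-12)
  expect_equal(round_half_up(d_snap$e_rho2, 2), 0.33)
})

test_that("printed-table mode reproduces the published coefficients at 2 decimals", {
  d_au <- dstudy_table(au, 2, 3, printed = TRUE)
  expect_equal(round_half_up(d_au$e_rho2, 2), 0.65)
  expect_equal(round_half_up(d_au$phi, 2), 0.47)
  d_c <- dstudy_table(cons_d, 2, 3, printed = TRUE)
  expect_equal(round_half_up(d_c$e_rho2, 2), 0.52)
  expect_equal(round_half_up(d_c$phi, 2), 0.27)
  # formatted table rounds coefficients to 2 decimals, components to 3
  ft <- format_dstudy(d_au)
  expect_equal(ft$estimate[ft$quantity == "e_rho2"], 0.65)
  expect_equal(ft$estimate[ft$quantity == "sigma2_r"], 0.060)
})

test_that("coefficient curves are nondecreasing and agree with point evaluations", {
  cv <- coefficient_curve(au, varying = "items", fixed_n = 3, max_n = 10)
  expect_equal(nrow(cv), 10)
  expect_true(all(diff(cv$coefficient) >= -1e-12))
  expect_equal(round_half_up(cv$coefficient[cv$n == 2], 2), 0.65)
  # independent arithmetic at n = 10 items, 3 raters
  v <- au$components
  delta10 <- v[["pi"]] / 10 + v[["pr"]] / 3 + v[["pir_e"]] / 30
  expect_equal(cv$coefficient[cv$n == 10],
               v[["p"]] / (v[["p"]] + delta10), tolerance = 1e-12)
})

test_that("minimal_design finds the smallest qualifying facet size", {
  noiseless <- variance_components(c(p = 1, i = 0, r = 0, pi = 0, pr = 0,
                                     ri = 0, pir_e = 0))
  expect_equal(minimal_design(noiseless, 0.8, "items", fixed_n = 3), 1L)
  # from the tabulated components, 5 items reach 0.80 with 3 raters
  n_star <- minimal_design(au, 0.80, "items", fixed_n = 3, cap = 10)
  expect_equal(n_star, 5L)
  expect_gte(coefficient_curve(au, "items", 3, 10)$coefficient[n_star], 0.80)
  expect_lt(coefficient_curve(au, "items", 3, 10)$coefficient[n_star - 1],
            0.80)
  # unreachable threshold
  expect_true(is.na(minimal_design(au, 0.999, "raters", fixed_n = 2,
                                   cap = 5)))
  expect_error(minimal_design(au, 1.2), "between 0 and 1")
})

test_that("coefficient invariants hold over randomized components and designs", {
  set.seed(99)
  for (k in 1:50) {
    vc <- random_components()
    n_i <- sample(1:10, 1); n_r <- sample(1:10, 1)
    d <- dstudy_table(vc, n_i, n_r)
    expect_lte(d$sigma2_delta, d$sigma2_Delta + 1e-15)
    expect_lte(d$phi, d$e_rho2 + 1e-12)
    expect_true(d$e_rho2 >= 0 && d$e_rho2 <= 1)
    expect_true(d$phi >= 0 && d$phi <= 1)
    # scale invariance of the coefficient ratios
    doubled <- variance_components(vc$components * 2)
    d2 <- dstudy_table(doubled, n_i, n_r)
    expect_equal(d2$e_rho2, d$e_rho2, tolerance = 1e-12)
    expect_equal(d2$phi, d$phi, tolerance = 1e-12)
  }
})
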
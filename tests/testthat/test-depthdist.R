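test_that("cumulative profiles are cumulative fractions at layer bottoms", {
  lay <- data.frame(top = c(0, 10), bottom = c(10, 20), frc = c(1, 1),
                    soc = c(1, 3))
  p <- cumulative_profile(lay, "FRC", site_id = "A")
  expect_equal(p$points, data.frame(d = c(10, 20), Y = c(0.5, 1.0)))
  p2 <- cumulative_profile(lay[1, ], "SOC", site_id = "A")
  expect_equal(p2$points, data.frame(d = 10, Y = 1))
  # zero-total profiles are excluded with a reason, not fitted
  lay0 <- transform(lay, frc = 0)
  p0 <- cumulative_profile(lay0, "FRC")
  expect_true(p0$excluded)
  expect_equal(p0$reason, "zero_total")
  est0 <- fit_beta(p0)
  expect_true(est0$excluded)
})

test_that("layers generated from a beta curve reproduce Y = 1 - beta^d", {
  lay <- beta_layers(0.95, seq(0, 200, by = 5))
  p <- profile_from_layers(lay)
  d <- p$points$d
  # exact on the truncated support, approximate against the open-ended curve
  expect_equal(p$points$Y, (1 - 0.95^d) / (1 - 0.95^200), tolerance = 1e-12)
  expect_equal(p$points$Y, 1 - 0.95^d, tolerance = 1e-4)
})

test_that("closed-form per-layer solution inverts the depth model", {
  expect_equal(solve_beta_point(0.5, 30), 0.5^(1 / 30))
  expect_equal(round(solve_beta_point(0.5, 30), 5), 0.97716)
  for (b0 in c(0.9, 0.95, 0.99)) {
    for (d in c(10, 30, 120))
      expect_equal(solve_beta_point(1 - b0^d, d), b0, tolerance = 1e-12)
  }
  expect_equal(solve_beta_point(1 - 0.6^30, 30), 0.6, tolerance = 1e-9)
  expect_true(is.na(solve_beta_point(0, 30)))
  expect_true(is.na(solve_beta_point(1, 30)))
  expect_error(solve_beta_point(0.5, 0), "d must be > 0")
})

test_that("noiseless profiles recover the generating beta to 1e-6", {
  for (b0 in c(0.90, 0.95, 0.98)) {
    est <- fit_beta(direct_profile(b0))
    expect_false(est$excluded)
    expect_equal(est$beta, b0, tolerance = 1e-6)
  }
  # shallower (bedrock-truncated) support works on its own depth range
  expect_equal(fit_beta(direct_profile(0.93, seq(10, 100, 10)))$beta, 0.93,
               tolerance = 1e-6)
  # layer-built profiles carry the truncated-support normalization, so the
  # open-ended model recovers beta only up to that small mismatch
  p <- profile_from_layers(beta_layers(0.95, seq(0, 200, by = 10)))
  expect_equal(fit_beta(p)$beta, 0.95, tolerance = 1e-4)
})

test_that("a single-point fit equals the closed form exactly", {
  p <- structure(list(site_id = "A", quantity = "FRC",
                      points = data.frame(d = 30, Y = 0.5),
                      excluded = FALSE, reason = NA_character_),
                 class = "cumulative_profile")
  est <- fit_beta(p, min_points = 1)
  expect_identical(est$beta, solve_beta_point(0.5, 30))
})

test_that("profiles with too few points are excluded with a reason", {
  lay <- beta_layers(0.95, c(0, 30, 200))
  est <- fit_beta(profile_from_layers(lay), min_points = 3)
  expect_true(est$excluded)
  expect_equal(est$reason, "too_few_points")
  expect_false(fit_beta(profile_from_layers(lay), min_points = 2)$excluded)
})

test_that("optimizer agrees with the exhaustive grid-search oracle", {
  set.seed(31)
  for (i in 1:25) {
    p <- noisy_profile(runif(1, 0.85, 0.99), cv = runif(1, 0, 0.3),
                       depth = sample(c(100, 140, 200), 1))
    est <- fit_beta(p)
    expect_lt(abs(est$beta - beta_grid_search(p)), 2e-4)
  }
})

test_that("beta is scale invariant and increases when mass moves deeper", {
  lay <- beta_layers(0.94, seq(0, 200, by = 20))
  b1 <- fit_beta(profile_from_layers(lay))$beta
  lay2 <- transform(lay, frc = frc * 37.5, soc = soc * 37.5)
  expect_equal(fit_beta(profile_from_layers(lay2))$beta, b1,
               tolerance = 1e-10)
  # shift 20% of the surface stock to the bottom layer
  lay3 <- lay
  shift <- 0.2 * lay3$frc[1]
  lay3$frc[1] <- lay3$frc[1] - shift
  lay3$frc[nrow(lay3)] <- lay3$frc[nrow(lay3)] + shift
  expect_gt(fit_beta(profile_from_layers(lay3))$beta, b1)
})

test_that("beta_table yields one row per site and quantity with explicit exclusions", {
  d <- synth_generate(synth_config(n_sites = c(forest = 5, grassland = 5),
                                   outlier_tundra = 0), seed = 13)
  stocks <- site_layer_stocks(d$tables)
  bt <- beta_table(stocks)
  expect_equal(nrow(bt), 20)
  expect_equal(sum(bt$excluded), 0)
  # a site with only 2 soil horizons loses its SOC beta but keeps the FRC
  # beta fit at root-increment resolution
  two <- data.frame(site_id = "Z", top = c(0, 50), bottom = c(50, 100),
                    is_organic = FALSE, frc = c(0.5, 0.1), soc = c(5, 1),
                    clay_pct = 10)
  fine <- data.frame(site_id = "Z", top = seq(0, 90, 10),
                     bottom = seq(10, 100, 10),
                     frc = (10:1) / 10)
  bt2 <- beta_table(two, increments = fine, min_points = 3)
  expect_true(bt2$excluded[bt2$quantity == "SOC"])
  expect_false(bt2$excluded[bt2$quantity == "FRC"])
  expect_equal(bt2$n_points[bt2$quantity == "FRC"], 10)
})

test_that("deeper-distributed generating betas yield larger estimates", {
  set.seed(77)
  shallow_cfg <- synth_config(
    n_sites = c(grassland = 10), outlier_tundra = 0, noise_cv = 0.05,
    beta_range = list(grassland = list(frc = c(0.92, 0.92),
                                       soc = c(0.92, 0.92))))
  deep_cfg <- synth_config(
    n_sites = c(grassland = 10), outlier_tundra = 0, noise_cv = 0.05,
    beta_range = list(grassland = list(frc = c(0.98, 0.98),
                                       soc = c(0.98, 0.98))))
  b_sh <- beta_table(site_layer_stocks(synth_generate(shallow_cfg, 21)$tables))
  b_dp <- beta_table(site_layer_stocks(synth_generate(deep_cfg, 22)$tables))
  expect_true(max(b_sh$beta) < min(b_dp$beta))   # cohorts do not overlap
})
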
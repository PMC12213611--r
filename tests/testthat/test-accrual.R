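test_that("standardization gives mean-zero unit-sd scores (sample sd)", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(4)
  for (i in 1:10) {
    z <- standardize(rnorm(sample(5:50, 1), sd = runif(1, 0.1, 10)))
    expect_equal(mean(z), 0, tolerance = 1e-12)
    expect_equal(sd(z), 1, tolerance = 1e-12)
  }
  expect_error(standardize(rep(2, 5), group = "deep/FRC"), "deep/FRC")
  expect_error(standardize(3), "fewer than 2")
})

test_that("1:1 residuals classify accrual above and priming below the line", {
  r <- one_to_one_residuals("A", "forest", "shallow", 0.5, 1.5)
  expect_equal(r$residual, 1.0)
  expect_equal(r$label, "accrual")
  r2 <- one_to_one_residuals(c("A", "B"), "forest", "deep",
                             c(0.3, -0.2), c(0.3, -0.2))
  expect_true(all(r2$residual == 0))
  expect_true(all(r2$label == "neutral"))
  # swapping the variables negates every residual
  set.seed(9)
  zf <- rnorm(8); zs <- rnorm(8)
  a <- one_to_one_residuals(letters[1:8], "x", "deep", zf, zs)
  b <- one_to_one_residuals(letters[1:8], "x", "deep", zs, zf)
  expect_equal(b$residual, -a$residual)
  expect_error(one_to_one_residuals("A", "x", "deep", c(1, 2), 1),
               "unpaired")
})

test_that("group residuals sum to zero and the partition is affine invariant", {
  d <- synth_generate(synth_config(), seed = 6)
  agg <- site_aggregates(d$tables)
  rec <- accrual_records(agg)
  for (cls in c("shallow", "deep"))
    expect_equal(sum(rec$residual[rec$depth_class == cls]), 0,
                 tolerance = 1e-9)
  # common affine rescaling of the raw stocks leaves labels unchanged
  agg2 <- agg
  for (v in c("frc_shallow", "frc_deep")) agg2[[v]] <- 3.7 * agg2[[v]] + 2
  for (v in c("soc_shallow", "soc_deep")) agg2[[v]] <- 0.4 * agg2[[v]] - 1
  rec2 <- accrual_records(agg2)
  expect_equal(rec2$label, rec$label)
  expect_equal(rec2$residual, rec$residual, tolerance = 1e-9)
})

test_that("by-ecosystem grouping standardizes within ecosystem class", {
  d <- synth_generate(synth_config(n_sites = c(forest = 6, grassland = 6),
                                   outlier_tundra = 0), seed = 10)
  agg <- site_aggregates(d$tables)
  rec <- accrual_records(agg, group = "by-ecosystem")
  sub <- rec$ecosystem == "forest" & rec$depth_class == "deep"
  expect_equal(mean(rec$z_frc[sub]), 0, tolerance = 1e-9)
  expect_equal(sd(rec$z_soc[sub]), 1, tolerance = 1e-9)
})

test_that("depth-class slopes match the normal-equations oracle", {
  d <- synth_generate(synth_config(n_sites = c(forest = 8, grassland = 8),
                                   outlier_tundra = 0), seed = 12)
  rec <- accrual_records(site_aggregates(d$tables))
  sc <- depth_slope_contrast(rec, "grassland")
  for (cls in c("shallow", "deep")) {
    sub <- rec[rec$ecosystem == "grassland" & rec$depth_class == cls, ]
    expect_equal(sc$slope[sc$depth_class == cls],
                 ols_oracle(sub$z_frc, sub$z_soc)[2], tolerance = 1e-10)
  }
  # exactly collinear records give slope 1 with essentially zero p
  col <- data.frame(site_id = letters[1:6], ecosystem = "grassland",
                    depth_class = "deep", z_frc = seq(-1, 1, length = 6))
  col$z_soc <- col$z_frc
  sc2 <- suppressWarnings(depth_slope_contrast(col, "grassland"))
  expect_equal(sc2$slope[sc2$depth_class == "deep"], 1, tolerance = 1e-12)
  expect_lt(sc2$p[sc2$depth_class == "deep"], 1e-12)
  # too few sites -> excluded with reason, not an error
  sc3 <- depth_slope_contrast(col[1:2, ], "grassland")
  expect_true(all(sc3$excluded[sc3$depth_class == "deep"] |
                    sc3$n[sc3$depth_class == "deep"] >= 3))
  expect_true(sc3$excluded[sc3$depth_class == "shallow"])
})

test_that("pure-noise FRC-SOC coupling yields slope CIs covering zero ~95% of the time", {
  set.seed(123)
  hits <- 0; R <- 300
  for (i in 1:R) {
    n <- 15
    zf <- standardize(rnorm(n)); zs <- standardize(rnorm(n))
    f <- lm(zs ~ zf)
    ci <- confint(f)[2, ]
    hits <- hits + (ci[1] <= 0 && 0 <= ci[2])
  }
  expect_gt(hits / R, 0.90)
  expect_lt(hits / R, 0.99)
})

test_that("residual regression recovers a known aridity effect", {
  # residual = 0.8 * aridity + noise; 95% CI coverage should be nominal
  set.seed(55)
  R <- 500; hits <- 0
  for (i in 1:R) {
    n <- 20
    cov <- data.frame(site_id = sprintf("s%02d", 1:n),
                      aridity = runif(n, 10, 120),
                      map = runif(n, 100, 2000),
                      clay_profile = runif(n, 5, 45),
                      micronutrient = rlnorm(n, 0, 0.4))
    rec <- data.frame(site_id = cov$site_id, ecosystem = "grassland",
                      depth_class = "shallow",
                      residual = 0.8 * cov$aridity + rnorm(n, 0, 8))
    fit <- explain_residuals(rec, cov)$fit
    ci <- confint(fit)["aridity", ]
    hits <- hits + (ci[1] <= 0.8 && 0.8 <= ci[2])
  }
  expect_gt(hits / R, 0.92)
  expect_lt(hits / R, 0.98)
})

test_that("residual regression diagnostics behave at the extremes", {
  n <- 12
  cov <- data.frame(site_id = sprintf("s%02d", 1:n),
                    aridity = seq(10, 120, length = n),
                    map = seq(200, 1800, length = n)^1.3,
                    clay_profile = rep(c(10, 20, 30), 4),
                    micronutrient = rep(c(0.5, 1.5), 6))
  rec <- data.frame(site_id = cov$site_id, ecosystem = "g",
                    depth_class = "deep",
                    residual = 2 + 0.5 * cov$aridity - 0.1 * cov$clay_profile)
  # zero-noise linear signal: adjusted R^2 is exactly 1
  out <- suppressWarnings(
    explain_residuals(rec, cov, terms = c("aridity", "clay_profile")))
  expect_equal(out$adj_r2, 1, tolerance = 1e-9)
  # collinear column is named in the error
  cov$dup <- 2 * cov$aridity
  expect_error(explain_residuals(rec, cov, terms = c("aridity", "dup")),
               "dup")
  # permuting covariates against residuals destroys the fit
  set.seed(77)
  r2 <- replicate(100, {
    perm <- cov[sample(n), ]
    perm$site_id <- cov$site_id
    explain_residuals(rec, perm, terms = c("aridity", "clay_profile"))$adj_r2
  })
  expect_lt(mean(r2), 0.25)
})
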
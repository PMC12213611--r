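test_that("stock formulas reproduce hand unit-conversion oracles", {
  # 1% C at bd 1 g/cm3 over 10 cm is 0.1 g C/cm2 = 1 kg C/m2
  expect_identical(soc_stock(1.0, 1.0, 10), 1.0)
  expect_identical(soc_stock(0, 1.3, 50), 0)
  expect_equal(soc_stock(2.5, 1.2, 20), 6.0)
  expect_identical(frc_stock(1000, 50), 0.5)
  expect_identical(frc_stock(0, 48), 0)
  expect_equal(frc_stock(420, 47.2), 0.19824)
  expect_error(soc_stock(-1, 1, 10), ">= 0")
  expect_error(frc_stock(-5, 50), ">= 0")
})

test_that("aridity index follows MAP/(MAT + 13) and is undefined at -13", {
  expect_equal(aridity_index(2500, 12), 100)
  expect_equal(aridity_index(0, 20), 0)
  expect_equal(aridity_index(100, -12), 100)   # driest, coldest corner
  expect_warning(out <- aridity_index(500, -13), "undefined")
  expect_true(is.na(out))
})

test_that("alignment apportions by overlap and conserves mass", {
  hz <- function(top, bottom) data.frame(
    top = top, bottom = bottom, is_organic = FALSE, oc_pct = 1,
    bulk_density = 1, clay_pct = 10)
  inc <- function(top, bottom, biomass) data.frame(
    top = top, bottom = bottom, biomass = biomass, root_c_pct = 50)

  # exact nesting: both increments land in the single horizon
  a <- align_roots_to_horizons(rbind(inc(0, 10, 100), inc(10, 20, 100)),
                               hz(c(0), c(20)))
  expect_equal(a$frc, frc_stock(200, 50))

  # straddling increment splits 5 cm / 5 cm
  b <- align_roots_to_horizons(inc(20, 30, 100), hz(c(0, 25), c(25, 100)))
  expect_equal(b$frc, c(frc_stock(50, 50), frc_stock(50, 50)))

  # horizon [0,25) over 10/10/10 g increments gets 10 + 10 + 5
  c3 <- align_roots_to_horizons(
    rbind(inc(0, 10, 10), inc(10, 20, 10), inc(20, 30, 10)),
    hz(c(0, 25), c(25, 30)))
  expect_equal(c3$frc[1], frc_stock(25, 50))

  expect_error(align_roots_to_horizons(inc(0, 10, 10), hz(0, 20)[0, ]),
               "empty")
})

test_that("root mass below horizon coverage goes to the remainder bucket", {
  hz <- data.frame(top = 0, bottom = 50, is_organic = FALSE, oc_pct = 1,
                   bulk_density = 1, clay_pct = 10)
  inc <- data.frame(top = c(0, 40), bottom = c(40, 80),
                    biomass = c(100, 100), root_c_pct = 50)
  a <- align_roots_to_horizons(inc, hz)
  # 10 of the 40 cm of the second increment is covered
  expect_equal(a$frc, frc_stock(100 + 25, 50))
  expect_equal(attr(a, "frc_below_coverage"), frc_stock(75, 50))
  expect_equal(sum(a$frc) + attr(a, "frc_below_coverage"),
               frc_stock(200, 50))
})

test_that("alignment is idempotent on coinciding boundaries and permutation invariant", {
  set.seed(42)
  hz <- data.frame(top = c(0, 30, 60), bottom = c(30, 60, 100),
                   is_organic = FALSE, oc_pct = c(3, 2, 1),
                   bulk_density = c(1, 1.2, 1.4), clay_pct = 15)
  inc <- data.frame(top = c(0, 30, 60), bottom = c(30, 60, 100),
                    biomass = c(300, 200, 100), root_c_pct = 48)
  a <- align_roots_to_horizons(inc, hz)
  expect_equal(a$frc, frc_stock(inc$biomass, 48))   # no redistribution
  p <- sample(3)
  a2 <- align_roots_to_horizons(inc[p, ], hz[p, ])
  expect_equal(a2, a)
})

test_that("site aggregates split at 30 cm proportionally and add up", {
  meta <- data.frame(site_id = "X", ecosystem = "grassland", mat = 10,
                     map = 600, litterfall = NA_real_,
                     max_profile_depth = 200)
  one <- data.frame(top = 0, bottom = 200, is_organic = FALSE,
                    frc = 1, soc = 10, clay_pct = 20)
  agg <- aggregate_site(one, meta)
  expect_equal(agg$frc_shallow, 30 / 200)
  expect_equal(agg$soc_shallow, 10 * 30 / 200)

  shallow_only <- data.frame(top = c(0, 10), bottom = c(10, 25),
                             is_organic = FALSE, frc = c(0.2, 0.1),
                             soc = c(2, 1), clay_pct = 20)
  agg2 <- aggregate_site(shallow_only, meta)
  expect_equal(agg2$frc_deep, 0)
  expect_equal(agg2$soc_deep, 0)

  om <- data.frame(top = c(0, 5), bottom = c(5, 100),
                   is_organic = c(TRUE, FALSE), frc = c(0.3, 0.7),
                   soc = c(2, 8), clay_pct = c(5, 25))
  agg3 <- aggregate_site(om, meta)
  expect_equal(agg3$frc_organic, 0.3)
  expect_equal(agg3$soc_organic, 2)
  expect_equal(agg3$frc_organic + agg3$frc_mineral, agg3$frc_total)
})

test_that("aggregation additivity holds across synthetic sites", {
  d <- synth_generate(synth_config(), seed = 5)
  agg <- site_aggregates(d$tables)
  expect_equal(agg$frc_total, agg$frc_organic + agg$frc_mineral,
               tolerance = 1e-9)
  expect_equal(agg$soc_total, agg$soc_organic + agg$soc_mineral,
               tolerance = 1e-9)
  expect_equal(agg$frc_total, agg$frc_shallow + agg$frc_deep,
               tolerance = 1e-9)
  expect_equal(agg$soc_total, agg$soc_shallow + agg$soc_deep,
               tolerance = 1e-9)
})

test_that("row order of the input tables never changes the outputs", {
  d <- synth_generate(synth_config(n_sites = c(forest = 3, grassland = 3),
                                   outlier_tundra = 0), seed = 8)
  t <- d$tables
  set.seed(1)
  t2 <- site_tables(t$sites[sample(nrow(t$sites)), ],
                    t$horizons[sample(nrow(t$horizons)), ],
                    t$roots[sample(nrow(t$roots)), ])
  a1 <- site_aggregates(t); a2 <- site_aggregates(t2)
  a2 <- a2[match(a1$site_id, a2$site_id), ]
  rownames(a2) <- NULL
  expect_equal(a2, a1)
})

test_that("live-only status filter drops dead biomass from FRC", {
  d <- synth_generate(synth_config(n_sites = c(grassland = 2),
                                   outlier_tundra = 0), seed = 2)
  all_st <- site_aggregates(d$tables, status = "all")
  live <- site_aggregates(d$tables, status = "live")
  expect_true(all(live$frc_total < all_st$frc_total))
  expect_equal(live$soc_total, all_st$soc_total)
})
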
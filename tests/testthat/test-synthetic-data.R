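test_that("generation is deterministic from the seed", {
  cfg <- scenario_config(seed = 42)
  p1 <- gen_species_pool(cfg)
  p2 <- gen_species_pool(cfg)
  expect_identical(p1$traits, p2$traits)
  expect_identical(p1$niche, p2$niche)
  r1 <- gen_units_and_records(p1, cfg)
  r2 <- gen_units_and_records(p2, cfg)
  expect_identical(r1, r2)
  # different seed, different draws
  p3 <- gen_species_pool(scenario_config(seed = 43))
  expect_false(identical(p1$traits$STI, p3$traits$STI))
  # site offsets do not disturb the caller's RNG stream
  set.seed(1); a <- rnorm(1)
  set.seed(1); invisible(site_offsets(cfg)); b <- rnorm(1)
  expect_identical(a, b)
})

test_that("species pool has the configured structure", {
  cfg <- scenario_config(seed = 7)
  pool <- gen_species_pool(cfg)
  expect_equal(nrow(pool$traits), 28)
  expect_equal(sum(pool$traits$socio_parasitic), 7)  # 0.25 * 28
  expect_setequal(names(pool$traits), c("species", trait_columns()))
  expect_false(any(pool$traits$socio_parasitic[1:2] == 1))  # not the complex
  # STI tracks the thermal optimum
  r <- cor(pool$traits$STI, pool$niche$t_opt)
  expect_gt(r, 0.9)
  # complex members resolvable through the registry
  expect_equal(normalize_species(pool$complex$members[1], pool$registry),
               pool$complex$label)
  # paired indicator columns are complements
  expect_equal(pool$traits$nest_above + pool$traits$nest_below, rep(1, 28))
  expect_equal(pool$traits$micro_wide + pool$traits$micro_cold, rep(1, 28))
})

test_that("records respect the occupancy model's extremes", {
  cfg <- scenario_config(seed = 5, parasite_multiplier = 0)
  pool <- gen_species_pool(cfg)
  rec <- gen_units_and_records(pool, cfg)
  parasites <- pool$niche$species[pool$niche$m_recent == 0]
  rec2020 <- rec[rec$year == 2020, ]
  expect_equal(sum(rec2020$species %in% parasites), 0)
  expect_gt(sum(rec$species %in% parasites), 0)  # present historically
  # counts are positive integers
  expect_true(all(rec$count >= 1))
  # schema matches the records-module contract
  expect_setequal(names(rec), c("species", "count", "site", "year",
                                "month", "day", "elev_low", "elev_high"))
  expect_true(all(rec$elev_low <= rec$elev_high))
})

test_that("presence probability 1 guarantees presence", {
  cfg <- scenario_config(seed = 2, n_species = 6,
                         p_max_range = c(1, 1), niche_width = 1e6,
                         parasite_fraction = 0)
  pool <- gen_species_pool(cfg)
  rec <- gen_units_and_records(pool, cfg)
  layout <- attr(rec, "layout")
  # every species recorded in every unit
  units_seen <- unique(rec[, c("site", "year", "elev_low", "elev_high")])
  per_unit <- tapply(rec$species,
                     paste(rec$site, rec$year,
                           findInterval(rec$elev_low, c(0, 1e9))), I)
  hist <- rec[rec$year != 2020, ]
  key <- paste(hist$site, hist$year, hist$elev_low)
  n_sp <- tapply(hist$species, key, function(s) length(unique(s)))
  expect_true(all(n_sp == 6))
})

test_that("empirical occupancy follows the Gaussian thermal response", {
  cfg <- scenario_config(seed = 31, parasite_fraction = 0,
                         p_max_range = c(0.8, 0.8))
  pool <- gen_species_pool(cfg)
  # many replicate draws of the same layout give the response curve
  sp <- pool$niche[10, ]
  probs <- numeric(0)
  expected <- numeric(0)
  set.seed(99)
  for (elev in seq(1200, 2800, by = 400)) {
    Tu <- beeshift:::spring_temp_at(cfg, elev, "historic")
    p_hat <- mean(runif(1000) <
                    sp$p_max * exp(-(Tu - sp$t_opt)^2 / (2 * sp$sigma^2)))
    p_true <- sp$p_max * exp(-(Tu - sp$t_opt)^2 / (2 * sp$sigma^2))
    probs <- c(probs, p_hat)
    expected <- c(expected, p_true)
  }
  # binomial error at n = 1000
  expect_true(all(abs(probs - expected) <
                    3 * sqrt(pmax(expected * (1 - expected), 1e-4) / 1000)))
})

test_that("synthetic climate has the configured structure", {
  cfg <- scenario_config(seed = 13, spatial_noise = 0)
  cl <- gen_climate(cfg, nx_fine = 10, ny_fine = 10,
                    years_coarse = 1950:2020, years_fine = 1961:2020)
  # zero noise, pre-ramp years: field is exactly seasonal + lapse structure
  v1 <- cl$fine$values[, , 7, 1]
  v2 <- cl$fine$values[, , 7, match(1970, cl$fine$years)]
  expect_equal(v1, v2, tolerance = 1e-12)   # no trend before the ramp
  mo_diff <- cl$fine$values[, , 7, 1] - cl$fine$values[, , 1, 1]
  expect_equal(mo_diff,
               matrix(cl$truth$seasonal[7] - cl$truth$seasonal[1], 10, 10),
               tolerance = 1e-12)
  # lapse structure: regressing a monthly field on elevation gives gamma
  b <- coef(lm(as.vector(cl$fine$values[, , 7, 1]) ~
                 as.vector(cl$fine$elev)))[2]
  expect_equal(unname(b) * 1000, cfg$lapse, tolerance = 1e-6)
  # coarse = aggregated truth with affine bias: fit_bias recovers it
  wts <- suppressWarnings(regrid_weights(cl$coarse, cl$fine, "bilinear"))
  expect_equal(dim(cl$coarse$values)[1:2], c(2, 2))
})

test_that("fit_bias recovers the configured coarse bias", {
  cfg <- scenario_config(seed = 17, spatial_noise = 0)
  cl <- gen_climate(cfg, nx_fine = 10, ny_fine = 10, coarse_factor = 5,
                    years_coarse = 1950:2020, years_fine = 1961:2020,
                    bias_slope = 0.9, bias_intercept = 0.8)
  # compare on the coarse grid itself: aggregate the fine truth
  agg <- function(m) {
    out <- matrix(0, 2, 2)
    for (i in 1:2) for (j in 1:2)
      out[i, j] <- mean(m[(i - 1) * 5 + 1:5, (j - 1) * 5 + 1:5])
    out
  }
  yrs <- 1961:1990
  fine_on_coarse <- array(0, c(2, 2, 12, 30))
  for (k in seq_along(yrs)) for (mo in 1:12)
    fine_on_coarse[, , mo, k] <-
      agg(cl$fine$values[, , mo, match(yrs[k], cl$fine$years)])
  fc <- monthly_grid(cl$coarse$x, cl$coarse$y, fine_on_coarse, yrs)
  cc <- monthly_grid(cl$coarse$x, cl$coarse$y,
                     cl$coarse$values[, , , match(yrs, cl$coarse$years)],
                     yrs)
  bias <- fit_bias(cc, fc, yrs)
  # coarse = 0.9 * truth + 0.8, so truth = (coarse - 0.8) / 0.9
  expect_equal(bias$slope, array(1 / 0.9, c(2, 2, 12)), tolerance = 1e-6)
  expect_equal(bias$intercept, array(-0.8 / 0.9, c(2, 2, 12)),
               tolerance = 1e-5)
})

test_that("ground truth reflects the configuration", {
  cfg <- scenario_config(seed = 3)
  pool <- gen_species_pool(cfg)
  gt <- ground_truth(pool, cfg)
  expect_equal(gt$warming, 1.76)
  expect_equal(gt$lapse, -6.68)
  expect_equal(unname(gt$richness["historic"]), 28)
  # all species have nonzero expected occupancy (Gaussian tails), so
  # richness truth counts species, but the parasite share must drop
  expect_lt(gt$parasite_share["recent"], gt$parasite_share["historic"])
  expect_equal(dim(gt$occupancy$historic),
               c(28, nrow(attr(gen_units_and_records(pool, cfg),
                               "layout"))))
})

test_that("estimated richness is lower in period 2 under decline", {
  # parasite multiplier 0.1 removes most parasites from period 2; the
  # detected (observed) richness drops. The Chao2 asymptote need not
  # drop: the surviving rare detections are uniques, and the estimator
  # correctly infers that the species pool still exists.
  lower <- 0
  for (s in 1:10) {
    cfg <- scenario_config(seed = 700 + s)
    pool <- gen_species_pool(cfg)
    rec <- gen_units_and_records(pool, cfg)
    fr <- filter_records(rec, filter_rules(
      allowed_years = unlist(cfg$periods), period_exclusions = list()))
    units <- pool_to_units(fr)
    inc <- build_incidence(units, pool$registry)
    rich <- vapply(split(seq_len(nrow(units)), units$period),
                   function(i) {
                     incidence_freqs(
                       inc[i, colSums(inc[i, , drop = FALSE]) > 0,
                           drop = FALSE])$S_obs
                   }, 0)
    if (rich["recent"] < rich["historic"]) lower <- lower + 1
  }
  expect_gte(lower, 8)
})
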
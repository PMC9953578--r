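grid2 <- function(n = 6, spacing = 5) {
  x <- (seq_len(n) - 0.5) * spacing
  list(x = x, y = x)
}

field_on <- function(g, fun) {
  xs <- rep(g$x, each = length(g$y))
  ys <- rep(g$y, times = length(g$x))
  matrix(mapply(fun, xs, ys), nrow = length(g$y))
}

test_that("regrid preserves constants and reproduces linear fields", {
  src <- grid2(6, 5)
  tgt <- grid2(25, 1.2)
  for (meth in c("patch_like", "bilinear")) {
    wts <- suppressWarnings(regrid_weights(src, tgt, meth))
    z_const <- field_on(src, function(x, y) 5)
    rf <- suppressWarnings(
      regrid(raster_field(src$x, src$y, z_const), tgt, meth,
             weights = wts))
    expect_equal(rf$z, field_on(tgt, function(x, y) 5), tolerance = 1e-9)
    # linear exactness at interior targets
    z_lin <- field_on(src, function(x, y) 2 * x + 3 * y)
    rf2 <- suppressWarnings(
      regrid(raster_field(src$x, src$y, z_lin), tgt, meth, weights = wts))
    interior <- tgt$x > min(src$x) & tgt$x < max(src$x)
    expect_equal(rf2$z[interior, interior],
                 field_on(tgt, function(x, y) 2 * x + 3 * y)[interior,
                                                             interior],
                 tolerance = 1e-7)
  }
})

test_that("patch interpolation beats bilinear on smooth curvature", {
  src <- grid2(8, 5)
  tgt <- grid2(70, 0.55)
  qf <- function(x, y) 0.02 * x^2 - 0.015 * y^2 + 0.01 * x * y
  z <- field_on(src, qf)
  truth <- field_on(tgt, qf)
  interior <- tgt$x > min(src$x) & tgt$x < max(src$x)
  err <- function(meth) {
    rf <- suppressWarnings(regrid(raster_field(src$x, src$y, z), tgt, meth))
    max(abs((rf$z - truth)[interior, interior]))
  }
  expect_lt(err("patch_like"), err("bilinear"))
  expect_lt(err("patch_like"), 1e-6)  # biquadratic is exact on quadratics
})

test_that("fit_bias recovers exact and noisy affine relations", {
  g <- grid2(4, 1)
  yrs <- 1961:1990
  arr <- array(rnorm(4 * 4 * 12 * 30, 5, 3), c(4, 4, 12, 30))
  coarse <- monthly_grid(g$x, g$y, arr, yrs)
  fine_same <- monthly_grid(g$x, g$y, arr, yrs)
  b0 <- fit_bias(coarse, fine_same, yrs)
  expect_equal(b0$slope, array(1, c(4, 4, 12)), tolerance = 1e-9)
  expect_equal(b0$intercept, array(0, c(4, 4, 12)), tolerance = 1e-9)
  fine_aff <- monthly_grid(g$x, g$y, 2 * arr + 1, yrs)
  b1 <- fit_bias(coarse, fine_aff, yrs)
  expect_equal(b1$slope, array(2, c(4, 4, 12)), tolerance = 1e-9)
  expect_equal(b1$intercept, array(1, c(4, 4, 12)), tolerance = 1e-9)
  expect_error(fit_bias(coarse, fine_aff, 1961:1965), ">= 10")
  # white noise sigma = 0.1 over 30 years: slope within 2 SE nearly always
  set.seed(5)
  noise <- array(rnorm(length(arr), 0, 0.1), dim(arr))
  bn <- fit_bias(coarse, monthly_grid(g$x, g$y, 2 * arr + 1 + noise, yrs),
                 yrs)
  cover <- 0; total <- 0
  for (mo in 1:12) for (i in 1:4) for (j in 1:4) {
    xs <- arr[i, j, mo, ]
    se <- 0.1 / sqrt(sum((xs - mean(xs))^2))
    total <- total + 1
    if (abs(bn$slope[i, j, mo] - 2) <= 2 * se * qt(0.975, 28) / 1.96 * 1.96)
      cover <- cover + 1
  }
  expect_gte(cover / total, 0.90)
})

test_that("apply_bias corrects early years and splices the fine data", {
  g <- grid2(3, 1)
  arr_c <- array(3, c(3, 3, 12, 4))
  coarse <- monthly_grid(g$x, g$y, arr_c, c(1959, 1960, 1961, 1962))
  arr_f <- array(10, c(3, 3, 12, 2))
  fine <- monthly_grid(g$x, g$y, arr_f, c(1961, 1962))
  bias <- structure(list(slope = array(2, c(3, 3, 12)),
                         intercept = array(1, c(3, 3, 12))),
                    class = "bias_model")
  fused <- apply_bias(coarse, fine, bias, splice_year = 1961)
  expect_equal(fused$years, c(1959, 1960, 1961, 1962))
  expect_equal(fused$values[1, 1, 1, 1], 7)    # 2*3 + 1
  expect_equal(fused$values[1, 1, 1, 3], 10)   # fine data from 1961 on
  # identity model leaves values unchanged
  id <- structure(list(slope = array(1, c(3, 3, 12)),
                       intercept = array(0, c(3, 3, 12))),
                  class = "bias_model")
  fused_id <- apply_bias(coarse, fine, id, splice_year = 1961)
  expect_equal(fused_id$values[, , , 1:2], arr_c[, , , 1:2])
})

test_that("splice continuity: corrected series matches fine on overlap", {
  cfg <- scenario_config(seed = 3, spatial_noise = 0.2)
  cl <- gen_climate(cfg, nx_fine = 10, ny_fine = 10, coarse_factor = 5,
                    years_coarse = 1950:1999, years_fine = 1961:1999)
  wts <- suppressWarnings(regrid_weights(cl$coarse, cl$fine, "patch_like"))
  cof <- suppressWarnings(regrid(cl$coarse, cl$fine, weights = wts))
  bias <- fit_bias(cof, cl$fine, 1961:1990)
  corr <- bias$slope[, , 1] * cof$values[, , 1, match(1975, cof$years)] +
    bias$intercept[, , 1]
  resid <- corr - cl$fine$values[, , 1, match(1975, cl$fine$years)]
  expect_lt(sqrt(mean(resid^2)), 3 * cfg$spatial_noise)
})

test_that("temperature_index averages the right months", {
  g <- grid2(2, 1)
  yrs <- 2000:2002
  arr <- array(0, c(2, 2, 12, 3))
  for (mo in 1:12) arr[, , mo, ] <- mo          # value = month number
  mg <- monthly_grid(g$x, g$y, arr, yrs)
  expect_equal(temperature_index(mg, "annual", 2001:2002)$z[1, 1],
               mean(1:12))
  expect_equal(temperature_index(mg, "spring", 2001:2002)$z[1, 1],
               mean(3:6))
  expect_equal(temperature_index(mg, "summer_half", 2001)$z[1, 1],
               mean(4:9))
  expect_equal(temperature_index(mg, "winter_half", 2001)$z[1, 1],
               mean(c(10:12, 1:3)))
  # constant series: every index equals the constant
  mg4 <- monthly_grid(g$x, g$y, array(4, c(2, 2, 12, 3)), yrs)
  for (idx in c("annual", "spring", "summer_half", "winter_half"))
    expect_equal(temperature_index(mg4, idx, 2001:2002)$z,
                 matrix(4, 2, 2))
  expect_error(temperature_index(mg, "winter_half", 2000), "not fully")
  expect_error(temperature_index(mg, "annual", 1999:2002), "not fully")
})

test_that("winter half-year crosses the year boundary correctly", {
  g <- grid2(2, 1)
  arr <- array(0, c(2, 2, 12, 2))
  arr[, , , 1] <- 1   # all of year 1 has value 1
  arr[, , , 2] <- 13  # all of year 2 has value 13
  mg <- monthly_grid(g$x, g$y, arr, 2000:2001)
  # winter 2001 = Oct-Dec 2000 (1) + Jan-Mar 2001 (13)
  expect_equal(temperature_index(mg, "winter_half", 2001)$z[1, 1],
               (3 * 1 + 3 * 13) / 6)
})

test_that("annual index combines the two half-year indices", {
  g <- grid2(2, 1)
  set.seed(8)
  per_month <- rnorm(12, 2, 4)
  arr <- array(rep(per_month, each = 4), c(2, 2, 12, 3))
  mg <- monthly_grid(g$x, g$y, arr, 2000:2002)  # year-stationary series
  ann <- temperature_index(mg, "annual", 2001:2002)$z
  sh <- temperature_index(mg, "summer_half", 2001:2002)$z
  wh <- temperature_index(mg, "winter_half", 2001:2002)$z
  expect_equal(ann, (sh + wh) / 2, tolerance = 1e-12)
})

test_that("downscale is exact on pure lapse fields and linear in warming", {
  src <- grid2(6, 5)
  z_src <- field_on(src, function(x, y) 1200 + 30 * x + 10 * y)
  dem_g <- grid2(40, 0.74)
  dem <- raster_field(dem_g$x, dem_g$y,
                      field_on(dem_g, function(x, y) 1300 + 25 * x))
  gamma <- -6.68
  fld <- structure(list(x = src$x, y = src$y,
                        z = gamma * z_src / 1000 + 2, index = "spring",
                        period = "p", elev = z_src),
                   class = c("index_field", "raster_field"))
  down <- suppressWarnings(downscale(fld, dem, lapse = gamma))
  expect_equal(down$z, gamma * dem$z / 1000 + 2, tolerance = 1e-9)
  # uniform warming shifts the downscaled field exactly
  fld2 <- fld
  fld2$z <- fld$z + 1.5
  down2 <- suppressWarnings(downscale(fld2, dem, lapse = gamma))
  expect_equal(down2$z, down$z + 1.5, tolerance = 1e-9)
  # two DEM cells 1000 m apart, zero residual: difference = gamma
  i <- which(abs(dem$z - dem$z[1, 1] - 1000) ==
               min(abs(dem$z - dem$z[1, 1] - 1000)))[1]
  expect_equal(down$z[i] - down$z[1, 1],
               gamma * (dem$z[i] - dem$z[1, 1]) / 1000, tolerance = 1e-9)
  fld$elev <- NULL
  expect_error(downscale(fld, dem), "no elevation")
})

test_that("equivalent_shift and glacier_change desk values", {
  expect_equal(equivalent_shift(1, -6.68), 1000 / 6.68)
  expect_equal(round(equivalent_shift(1, -6.68), 1), 149.7)
  expect_equal(round(equivalent_shift(1.76, -6.68), 1), 263.5)
  expect_equal(equivalent_shift(0, -6.68), 0)
  expect_error(equivalent_shift(1, 0), "zero")
  expect_equal(round(glacier_change(26.8, 8.4), 2), 68.66)
  expect_equal(glacier_change(10, 10), 0)
  expect_equal(glacier_change(10, 5), 50)
  expect_equal(glacier_change(10, 12), -20)  # growth reported as negative
})

test_that("zone_means has closed form on lapse fields", {
  g <- grid2(10, 1)
  dem <- raster_field(g$x, g$y,
                      field_on(g, function(x, y) 1000 + 150 * x))
  gamma <- -6.68
  fld <- raster_field(g$x, g$y, gamma * dem$z / 1000 + 3)
  zm <- zone_means(fld, dem, list(c(1900, 2000)))
  sel <- dem$z >= 1900 & dem$z <= 2000
  expect_equal(unname(zm), gamma * mean(dem$z[sel]) / 1000 + 3)
  # single-cell zone and whole-domain zone
  zm2 <- zone_means(fld, dem, list(c(min(dem$z), min(dem$z)),
                                   range(dem$z)))
  expect_equal(unname(zm2[1]), fld$z[which.min(dem$z)])
  expect_equal(unname(zm2[2]), mean(fld$z))
  expect_error(zone_means(fld, dem, list(c(9000, 9999))), "empty")
})

test_that("ascii grid round-trips through read/write", {
  g <- grid2(5, 2)
  z <- field_on(g, function(x, y) x - 2 * y + 0.25)
  p <- tempfile(fileext = ".asc")
  write_ascii_grid(raster_field(g$x, g$y, z), p)
  got <- read_ascii_grid(p)
  expect_equal(sort(got$x), sort(g$x))
  # northernmost row first on disk; container is y-ascending or descending
  expect_equal(got$z[order(-got$y), order(got$x)], z[order(-g$y), ],
               tolerance = 1e-9)
})

test_that("full fusion-bias-index-downscale recovers the warming", {
  # zero noise: within 0.05 K
  cfg0 <- scenario_config(seed = 11, spatial_noise = 0)
  w0 <- suppressWarnings(run_climate_recovery(cfg0))
  expect_lt(abs(w0 - 1.76), 0.05)
  # noise sigma = 0.5 K: within 0.2 K
  cfg1 <- scenario_config(seed = 12, spatial_noise = 0.5)
  w1 <- suppressWarnings(run_climate_recovery(cfg1))
  expect_lt(abs(w1 - 1.76), 0.2)
})
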
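test_that("normalize_species resolves synonyms, complexes and drop list", {
  reg <- demo_registry()
  expect_equal(normalize_species("B. lucorum", reg),
               "B. lucorum/cryptarum complex")
  expect_equal(normalize_species("B. cryptarum", reg),
               "B. lucorum/cryptarum complex")
  expect_equal(normalize_species("B. alpinus", reg), "B. alpinus")
  expect_equal(normalize_species("B. lapponicus alpinus", reg),
               "B. alpinus")
  expect_true(is.na(normalize_species("B. sp.", reg)))
  expect_error(normalize_species("B. martianus", reg), "B. martianus")
  # vectorized and deterministic
  v <- normalize_species(c("B. lucorum", "B. alpinus", "B. sp."), reg)
  expect_equal(v, c("B. lucorum/cryptarum complex", "B. alpinus", NA))
})

test_that("filter_records applies each exclusion rule and logs counts", {
  recs <- records_df(
    rec_row(),                                    # kept
    rec_row(elev_low = 1100, elev_high = 1700),   # span 600 -> out
    rec_row(elev_low = 1500, elev_high = 2000),   # span exactly 500 -> kept
    rec_row(elev_low = 2950, elev_high = 3000),   # above window -> out
    rec_row(year = 1937),                         # year -> out
    rec_row(month = NA, day = NA),                # no date -> out
    rec_row(species = "B. mesomelas"),            # period exclusion -> out
    rec_row(species = "B. mesomelas", year = 2020,
            elev_low = 1900, elev_high = 1950))   # only historic excluded
  out <- filter_records(recs, filter_rules())
  log <- attr(out, "exclusion_log")
  expect_equal(nrow(out), 3)
  expect_equal(unname(log["elev_span"]), 1)
  expect_equal(unname(log["elev_window"]), 1)
  expect_equal(unname(log["year"]), 1)
  expect_equal(unname(log["no_date"]), 1)
  expect_equal(unname(log["species_period"]), 1)
  expect_true("B. mesomelas" %in% out$species)  # the 2020 record survives
})

test_that("nest-excavation heuristic removes single-species mass records", {
  nest <- rec_row(species = "B. monticola", count = 35,
                  site = "LT", day = 3)
  multi <- records_df(
    rec_row(species = "B. monticola", count = 35, site = "KT", day = 4),
    rec_row(species = "B. alpinus", count = 2, site = "KT", day = 4))
  out <- filter_records(records_df(rec_row(), nest, multi), filter_rules())
  expect_false(any(out$site == "LT"))             # lone mass record dropped
  expect_equal(sum(out$site == "KT"), 2)          # accompanied one kept
  expect_equal(unname(attr(out, "exclusion_log")["nest_excavation"]), 1)
  # below threshold is kept
  out2 <- filter_records(records_df(rec_row(count = 29, site = "FH")),
                         filter_rules())
  expect_equal(nrow(out2), 1)
})

test_that("filtering is idempotent", {
  set.seed(3)
  recs <- do.call(rbind, lapply(1:40, function(i)
    rec_row(species = sample(c("B. alpinus", "B. monticola"), 1),
            count = sample(c(NA, 1:40), 1),
            site = sample(c("KBT", "LT"), 1),
            year = sample(c(1935, 1936, 1937, 2020), 1),
            elev_low = el <- sample(seq(1000, 2800, 50), 1),
            elev_high = el + sample(c(0, 100, 400, 600), 1))))
  once <- filter_records(recs, filter_rules())
  twice <- filter_records(once, filter_rules())
  expect_equal(twice$species, once$species)
  expect_equal(twice$elev_low, once$elev_low)
})

test_that("pool_to_units merges redundant intervals and re-bins 2020", {
  recs <- records_df(
    rec_row(species = "B. alpinus", elev_low = 1900, elev_high = 2000),
    rec_row(species = "B. monticola", elev_low = 1800, elev_high = 2000),
    rec_row(species = "B. pratorum", year = 2020,
            elev_low = 1850, elev_high = 1850))
  units <- pool_to_units(recs)
  expect_equal(nrow(units), 2)
  hist <- units[units$year == 1935, ]
  expect_equal(hist$elev_low, 1800)      # 1900-2000 and 1800-2000 merged
  expect_equal(hist$elev_high, 2000)
  expect_equal(hist$mean_elev, 1900)
  expect_equal(hist$id, "1935#KBT#1900MSL")
  expect_setequal(hist$species[[1]], c("B. alpinus", "B. monticola"))
  # recent record re-binned into the historical interval
  rec2020 <- units[units$year == 2020, ]
  expect_equal(rec2020$elev_low, 1800)
  expect_equal(rec2020$id, "2020#KBT#1900MSL")
})

test_that("unit ids, midpoints and species unions are as specified", {
  units <- pool_to_units(records_df(
    rec_row(species = "B. alpinus"),
    rec_row(species = "B. monticola")))
  expect_equal(nrow(units), 1)
  expect_equal(units$mean_elev, 1950)
  expect_equal(units$id, "1935#KBT#1950MSL")
  expect_equal(units$n_species, 2)
})

test_that("recent records outside all historical bins are dropped+logged", {
  recs <- records_df(
    rec_row(),
    rec_row(year = 2020, elev_low = 2500, elev_high = 2500),
    rec_row(year = 2020, site = "ZZ", elev_low = 1950, elev_high = 1950))
  units <- pool_to_units(recs)
  expect_equal(attr(units, "dropped_recent"), 2)
  expect_equal(nrow(units), 1)
})

test_that("re-binning ties go to the lower bin", {
  recs <- records_df(
    rec_row(elev_low = 1800, elev_high = 1900),
    rec_row(species = "B. monticola", elev_low = 1900, elev_high = 2000),
    rec_row(species = "B. pratorum", year = 2020,
            elev_low = 1900, elev_high = 1900))  # midpoint on both bins
  units <- pool_to_units(recs)
  u2020 <- units[units$year == 2020, ]
  expect_equal(u2020$elev_low, 1800)
})

test_that("pooling is order-independent", {
  set.seed(11)
  recs <- do.call(rbind, lapply(1:60, function(i) {
    el <- sample(seq(1200, 2600, 200), 1)
    rec_row(species = sample(c("B. alpinus", "B. monticola",
                               "B. pratorum"), 1),
            site = sample(c("KBT", "LT", "KT"), 1),
            year = sample(c(1935, 2020), 1),
            elev_low = el, elev_high = el + sample(c(100, 300), 1))
  }))
  u1 <- pool_to_units(recs)
  u2 <- pool_to_units(recs[sample(nrow(recs)), ])
  expect_equal(u1$id, u2$id)
  expect_equal(u1$species, u2$species)
  expect_equal(build_incidence(u1), build_incidence(u2))
})

test_that("build_incidence constructs binary matrix with provenance", {
  recs <- records_df(
    rec_row(species = "B. alpinus", count = 1),
    rec_row(species = "B. monticola", count = 47),
    rec_row(species = "B. monticola", site = "LT"),
    rec_row(species = "B. pratorum", site = "LT"))
  units <- pool_to_units(recs)
  m <- build_incidence(units)
  expect_equal(dim(m), c(2, 3))
  expect_equal(unname(rowSums(m)), c(2, 2))
  expect_true(all(m %in% 0:1))             # counts 1 and 47 both collapse
  # every cell traces to >= 1 surviving record
  prov <- attr(units, "provenance")
  expect_true(all(lengths(prov) >= 1))
  for (u in units$id) {
    got <- sort(unique(recs[prov[[u]], "species"]))
    expect_equal(got, units[u, "species"][[1]])
  }
})

test_that("build_incidence normalizes via registry and drops zero columns", {
  recs <- records_df(
    rec_row(species = "B. lucorum"),
    rec_row(species = "B. cryptarum"),
    rec_row(species = "B. sp.", site = "LT"))
  units <- pool_to_units(recs)
  expect_warning(m <- build_incidence(units, demo_registry()),
                 "no species")
  expect_equal(colnames(m), "B. lucorum/cryptarum complex")
  expect_equal(nrow(m), 2)  # empty LT unit retained as all-zero row
  expect_equal(unname(m[, 1]), c(1L, 0L))
})

test_that("record CSV round-trips through read_records", {
  recs <- records_df(rec_row(), rec_row(species = "B. monticola",
                                        elev_low = 2100, elev_high = NA))
  p <- tempfile(fileext = ".csv")
  write.csv(recs, p, row.names = FALSE)
  got <- read_records(p)
  expect_equal(got$species, recs$species)
  expect_equal(got$elev_high[2], 2100)  # point record filled
  expect_error(read_records({
    p2 <- tempfile(fileext = ".csv")
    write.csv(recs[, -1], p2, row.names = FALSE); p2
  }), "missing column")
})
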
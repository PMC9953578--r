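#' Scenario configuration for the synthetic resurvey world
#'
#' Defaults describe the emulated survey: ~28 species (two of which form an
#' unresolvable complex) with Gaussian thermal niches, 11 sites spanning
#' 1100-2899 masl with coarse historical elevation bins, two sampling
#' periods separated by a configured spring warming, a linear vertical
#' temperature gradient, and a strong between-period decline of
#' socio-parasitic species.
#'
#' @param n_species number of species in the pool (>= 5; default 28).
#' @param parasite_fraction fraction flagged socio-parasitic (default 0.25;
#'   the count is `round(fraction * n_species)`).
#' @param sites character vector of site codes (default the 11 survey
#'   sites).
#' @param elev_range study elevation window in masl.
#' @param bins_per_site coarse historical elevation bins per site.
#' @param bin_widths candidate historical bin widths in meters.
#' @param periods named list of years per period.
#' @param warming between-period spring warming in K (default 1.76).
#' @param lapse vertical temperature gradient in K/km (default -6.68).
#' @param spring_t0 spring temperature at sea level in degrees C
#'   (default 14, giving about +6.6 C at 1100 m and -5.4 C at 2900 m).
#' @param spatial_noise sd of transient cell-level temperature noise in K
#'   (default 0.5).
#' @param site_offset_sd sd of the persistent site-level temperature
#'   deviation in K (aspect/microclimate differences between sites at equal
#'   elevation; default 0.8).
#' @param niche_width thermal niche sd in K (default 2.5).
#' @param p_max_range range of per-species maximum occupancy.
#' @param parasite_multiplier period-2 occupancy multiplier for parasites
#'   (default 0.1).
#' @param count_lambda mean of the zero-truncated Poisson for counts.
#' @param niche_model `"gaussian"` (default) or `"logistic"`.
#' @param seed scenario seed; every generator derives its stream from it.
#' @return list of class `scenario_config`.
#' @export
scenario_config <- function(n_species = 28,
                            parasite_fraction = 0.25,
                            sites = c("KBT", "LT", "KT", "FS", "TS", "DT",
                                      "RS", "KMT", "SL", "FH", "GG"),
                            elev_range = c(1100, 2899),
                            bins_per_site = 2,
                            bin_widths = c(200, 300, 400, 500),
                            periods = list(historic = c(1935L, 1936L),
                                           recent = 2020L),
                            warming = 1.76,
                            lapse = -6.68,
                            spring_t0 = 14,
                            spatial_noise = 0.5,
                            site_offset_sd = 0.8,
                            niche_width = 2.5,
                            p_max_range = c(0.6, 0.9),
                            parasite_multiplier = 0.1,
                            count_lambda = 3,
                            niche_model = c("gaussian", "logistic"),
                            seed = 1L) {
  stopifnot(n_species >= 5, lapse < 0, niche_width > 0)
  structure(list(n_species = n_species,
                 parasite_fraction = parasite_fraction,
                 sites = sites, elev_range = elev_range,
                 bins_per_site = bins_per_site, bin_widths = bin_widths,
                 periods = periods, warming = warming, lapse = lapse,
                 spring_t0 = spring_t0, spatial_noise = spatial_noise,
                 site_offset_sd = site_offset_sd,
                 niche_width = niche_width, p_max_range = p_max_range,
                 parasite_multiplier = parasite_multiplier,
                 count_lambda = count_lambda,
                 niche_model = match.arg(niche_model),
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# spring temperature implied by the analytic lapse structure (without the
# persistent site-level deviation)
spring_temp_at <- function(config, elev_m, period) {
  config$spring_t0 + config$lapse * elev_m / 1000 +
    ifelse(period == "recent", config$warming, 0)
}

#' Persistent site-level temperature offsets of a scenario
#'
#' Each site deviates from the pure lapse structure by a time-constant
#' temperature offset (exposure, aspect, cold-air pooling). The offsets are
#' a deterministic function of the scenario seed and leave the caller's
#' random number stream untouched.
#'
#' @param config a [scenario_config()].
#' @param component `"spring"` (default) or `"annual"`: the two seasons
#'   carry different persistent spatial patterns (e.g. cold-air pooling
#'   shapes winter but not spring temperatures).
#' @return named numeric vector, one offset (K) per site.
#' @export
site_offsets <- function(config, component = c("spring", "annual")) {
  component <- match.arg(component)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(config$seed + if (component == "spring") 9L else 10L)
  stats::setNames(stats::rnorm(length(config$sites), 0,
                               config$site_offset_sd), config$sites)
}

# full synthetic truth: lapse structure + persistent site deviation
true_spring_temp <- function(config, site, elev_m, period) {
  spring_temp_at(config, elev_m, period) + site_offsets(config)[site]
}

ztpois <- function(n, lambda) {
  # zero-truncated Poisson by inversion of the conditional CDF
  u <- stats::runif(n)
  stats::qpois(stats::ppois(0, lambda) + u * (1 - stats::ppois(0, lambda)),
               lambda)
}

#' Generate the species pool: registry, traits and niche parameters
#'
#' Species are laid out along the thermal gradient: thermal optima cover
#' the realized spring-temperature range, STI is the optimum plus small
#' noise, and categorical traits correlate with the optimum (cold/alpine
#' preferences for cold-adapted species). The first two species are emitted
#' as an unresolvable pair (members of a *lucorum/cryptarum*-style
#' complex) to exercise complex handling; one historical-only synonym is
#' included in the registry.
#'
#' @param config a [scenario_config()].
#' @param seed overrides `config$seed` when given.
#' @return list: `registry` ([species_registry()]), `traits` (data.frame,
#'   one row per member species), `niche` (data.frame: `species`, `t_opt`,
#'   `sigma`, `p_max`, `m_recent`), `complex` (label + members).
#' @export
gen_species_pool <- function(config, seed = config$seed) {
  set.seed(as.integer(seed))
  n <- config$n_species
  nm <- sprintf("B. synthetica%02d", seq_len(n))
  nm[1:2] <- c("B. lucorum (synthetic)", "B. cryptarum (synthetic)")
  complex_label <- "B. lucorum/cryptarum complex (synthetic)"

  t_range <- spring_temp_at(config, rev(config$elev_range), "historic")
  # two thermal guilds (montane vs alpine communities straddling the tree
  # boundary) with within-guild scatter, mirroring the two-stratum
  # structure of alpine bumblebee assemblages
  centers <- t_range[1] + c(0.28, 0.72) * diff(t_range)
  guild <- rep_len(1:2, n)
  t_opt <- centers[guild] + stats::rnorm(n, 0, 1.2)
  t_opt[2] <- t_opt[1] + stats::rnorm(1, 0, 0.3)  # complex members alike
  n_par <- round(config$parasite_fraction * n)
  # parasites scattered over the gradient, never the complex members
  parasites <- sort(sample(3:n, n_par))
  p_max <- stats::runif(n, config$p_max_range[1], config$p_max_range[2])
  m_recent <- ifelse(seq_len(n) %in% parasites,
                     config$parasite_multiplier, 1)

  cold <- t_opt < stats::median(t_opt)
  flip <- function(x, p = 0.2) ifelse(stats::runif(n) < p, 1 - x, x)
  nest_below <- flip(as.numeric(cold))          # cold-adapted nest below
  habitat_open <- flip(as.numeric(cold))        # open alpine vs forest edge
  micro_cold <- flip(as.numeric(cold), 0.15)
  macro_alpine <- flip(as.numeric(cold), 0.15)
  traits <- data.frame(
    species = nm,
    proboscis_length = round(stats::rnorm(n, 9, 1.5), 2),
    body_size = round(stats::rnorm(n, 16, 2), 2),
    nest_above = 1 - nest_below,
    nest_below = nest_below,
    socio_parasitic = as.numeric(seq_len(n) %in% parasites),
    habitat_open = habitat_open,
    habitat_forest_edge = 1 - habitat_open,
    STI = round(t_opt + stats::rnorm(n, 0, 0.3), 2),
    micro_wide = 1 - micro_cold,
    micro_cold = micro_cold,
    macro_indiscriminate = 1 - macro_alpine,
    macro_alpine = macro_alpine,
    stringsAsFactors = FALSE)
  rownames(traits) <- nm

  registry <- species_registry(
    canonical = c(nm, complex_label),
    synonyms = stats::setNames(nm[3], "B. synthetica03 var. antiqua"),
    complexes = stats::setNames(list(nm[1:2]), complex_label),
    parasites = nm[parasites],
    drop = "B. sp.")

  list(registry = registry, traits = traits,
       niche = data.frame(species = nm, t_opt = t_opt,
                          sigma = config$niche_width, p_max = p_max,
                          m_recent = m_recent, stringsAsFactors = FALSE),
       complex = list(label = complex_label, members = nm[1:2]))
}

# site layout: base elevations spread over the study window, each site
# carrying `bins_per_site` stacked coarse historical bins
site_layout <- function(config) {
  ns <- length(config$sites)
  lo <- config$elev_range[1]; hi <- config$elev_range[2]
  base <- round(seq(lo, hi - 600, length.out = ns) / 50) * 50
  widths <- config$bin_widths[1 + (seq_len(ns * config$bins_per_site) - 1) %%
                                length(config$bin_widths)]
  out <- list()
  k <- 0
  for (i in seq_len(ns)) {
    b <- base[i]
    for (j in seq_len(config$bins_per_site)) {
      k <- k + 1
      w <- widths[k]
      low <- min(b, hi - w)
      out[[k]] <- data.frame(site = config$sites[i], bin = j,
                             elev_low = low,
                             elev_high = min(low + w, hi))
      b <- low + w + 100  # gap keeps a site's coarse bins distinct
    }
  }
  do.call(rbind, out)
}

#' Generate occurrence records for the scenario
#'
#' For every (site, elevation bin, period) sampling unit and species,
#' presence is Bernoulli with probability
#' `p_max * response(T_unit - T_opt) * m_period`, where the response is
#' Gaussian (default) in the unit's spring temperature; counts of present
#' species are zero-truncated Poisson. Historical records carry the coarse
#' bin as their elevation interval; recent records carry narrow (100 m)
#' intervals inside the bin, exercising the re-binning step. Each site's
#' historical records come from one of the historical years.
#'
#' @param pool output of [gen_species_pool()].
#' @param config a [scenario_config()].
#' @param temps optional function `(site, elev_m, period) -> spring
#'   temperature`; defaults to the analytic lapse structure of the
#'   scenario plus the persistent [site_offsets()].
#' @param seed overrides `config$seed + 1` when given.
#' @return data.frame in the occurrence-record CSV schema; the generating
#'   unit layout is in attribute `"layout"`.
#' @export
gen_units_and_records <- function(pool, config, temps = NULL,
                                  seed = config$seed + 1L) {
  set.seed(as.integer(seed))
  if (is.null(temps))
    temps <- function(site, elev_m, period)
      true_spring_temp(config, site, elev_m, period)
  layout <- site_layout(config)
  hist_years <- config$periods$historic
  site_year <- stats::setNames(
    sample(hist_years, length(config$sites), replace = TRUE), config$sites)
  response <- function(dT) {
    if (config$niche_model == "gaussian")
      exp(-dT^2 / (2 * config$niche_width^2))
    else 1 / (1 + exp((abs(dT) - 2 * config$niche_width) /
                        (config$niche_width / 4)))
  }
  rows <- list()
  for (b in seq_len(nrow(layout))) {
    mid <- (layout$elev_low[b] + layout$elev_high[b]) / 2
    for (period in names(config$periods)) {
      yr <- if (period == "historic") site_year[[layout$site[b]]] else
        config$periods[[period]][1]
      Tu <- temps(layout$site[b], mid, period)
      pr <- pool$niche$p_max * response(Tu - pool$niche$t_opt) *
        (if (period == "recent") pool$niche$m_recent else 1)
      present <- which(stats::runif(nrow(pool$niche)) < pr)
      if (!length(present)) next
      cnt <- ztpois(length(present), config$count_lambda)
      if (period == "historic") {
        elo <- layout$elev_low[b]; ehi <- layout$elev_high[b]
      } else {
        # narrow 100 m transect intervals within the historical bin
        lo100 <- 100 * floor(layout$elev_low[b] / 100)
        starts <- seq(lo100, layout$elev_high[b] - 100, by = 100)
        s <- sample(starts, length(present), replace = TRUE)
        elo <- pmax(s, layout$elev_low[b])
        ehi <- pmin(s + 100, layout$elev_high[b])
      }
      rows[[length(rows) + 1]] <- data.frame(
        species = pool$niche$species[present],
        count = cnt,
        site = layout$site[b],
        year = yr,
        month = sample(7:8, length(present), replace = TRUE),
        day = sample(1:28, length(present), replace = TRUE),
        elev_low = elo, elev_high = ehi,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "layout") <- layout
  out
}

#' Generate the two-resolution synthetic climate world
#'
#' Truth field: `T(x, y, month, year) = seasonal(month) + ramp(year) +
#' lapse * z(x, y) + noise`, on a fine grid with a smooth synthetic valley
#' DEM. The coarse dataset is the block-averaged truth with an affine bias
#' applied; the fine dataset is the truth restricted to the recent span.
#' The warming ramp is scaled so that the between-period spring
#' (March-June) difference equals `config$warming` exactly in expectation.
#'
#' @param config a [scenario_config()].
#' @param seed overrides `config$seed + 2` when given.
#' @param nx_fine,ny_fine fine grid size (default 30 x 30, spacing 1 km).
#' @param coarse_factor cells aggregated per coarse cell (default 5).
#' @param dem_factor DEM refinement per fine cell (default 2).
#' @param years_coarse,years_fine temporal coverage.
#' @param bias_slope,bias_intercept affine bias of the coarse dataset.
#' @return list: `coarse`, `fine` (`monthly_grid`s), `dem`
#'   (`raster_field`), `truth` (ramp weights, seasonal cycle, bias, warming
#'   amplitude).
#' @export
gen_climate <- function(config, seed = config$seed + 2L,
                        nx_fine = 30, ny_fine = 30, coarse_factor = 5,
                        dem_factor = 2,
                        years_coarse = 1905:2020, years_fine = 1961:2020,
                        bias_slope = 0.95, bias_intercept = 0.5) {
  set.seed(as.integer(seed))
  fx <- seq_len(nx_fine) - 0.5
  fy <- seq_len(ny_fine) - 0.5
  # smooth valley DEM: elevation rises from the valley axis to the flanks
  zfun <- function(x, y) {
    cx <- nx_fine / 2
    1100 + 1500 * ((outer(rep(1, length(y)), x) - cx) / nx_fine)^2 +
      900 * (outer(y, rep(1, length(x))) / ny_fine)
  }
  z_fine <- zfun(fx, fy)

  seasonal <- -8 * cos(2 * pi * (1:12 - 0.5) / 12)  # January coldest
  w <- ifelse(years_coarse <= 1975, 0,
              pmin((years_coarse - 1975) / 30, 1))  # ramp 1976-2005
  p1y <- intersect(1906:1935, years_coarse)
  p2y <- intersect(1991:2020, years_coarse)
  if (length(p1y) < 5) p1y <- utils::head(years_coarse, 30)
  if (length(p2y) < 5) p2y <- utils::tail(years_coarse, 30)
  p1 <- match(p1y, years_coarse)
  p2 <- match(p2y, years_coarse)
  amp <- config$warming / (mean(w[p2]) - mean(w[p1]))

  ny <- length(years_coarse)
  vals <- array(0, dim = c(ny_fine, nx_fine, 12, ny))
  base <- config$spring_t0 - mean(seasonal[3:6]) +
    config$lapse * z_fine / 1000
  for (iy in seq_len(ny)) for (mo in 1:12) {
    vals[, , mo, iy] <- base + seasonal[mo] + amp * w[iy] +
      if (config$spatial_noise > 0)
        matrix(stats::rnorm(ny_fine * nx_fine, 0, config$spatial_noise),
               ny_fine, nx_fine)
      else 0
  }
  fine <- monthly_grid(fx, fy, vals[, , , match(years_fine, years_coarse),
                                    drop = FALSE],
                       years_fine, elev = z_fine)

  # coarse: block-average the truth, then apply an affine bias
  nxc <- nx_fine %/% coarse_factor
  nyc <- ny_fine %/% coarse_factor
  cx <- (seq_len(nxc) - 0.5) * coarse_factor
  cy <- (seq_len(nyc) - 0.5) * coarse_factor
  agg <- function(m) {
    out <- matrix(0, nyc, nxc)
    for (i in seq_len(nyc)) for (j in seq_len(nxc))
      out[i, j] <- mean(m[(i - 1) * coarse_factor + seq_len(coarse_factor),
                          (j - 1) * coarse_factor + seq_len(coarse_factor)])
    out
  }
  cvals <- array(0, dim = c(nyc, nxc, 12, ny))
  for (iy in seq_len(ny)) for (mo in 1:12)
    cvals[, , mo, iy] <- bias_slope * agg(vals[, , mo, iy]) + bias_intercept
  coarse <- monthly_grid(cx, cy, cvals, years_coarse, elev = agg(z_fine))

  dx <- seq(0, nx_fine, by = 1 / dem_factor)
  dx <- dx[dx > 0 & dx < nx_fine]
  dy <- seq(0, ny_fine, by = 1 / dem_factor)
  dy <- dy[dy > 0 & dy < ny_fine]
  dem <- raster_field(dx, dy, zfun(dx, dy))

  list(coarse = coarse, fine = fine, dem = dem,
       truth = list(ramp = w, seasonal = seasonal, amplitude = amp,
                    warming = config$warming,
                    bias_slope = bias_slope,
                    bias_intercept = bias_intercept,
                    lapse = config$lapse))
}

#' Parameter-recovery study over replicate synthetic worlds
#'
#' Replays the full analysis over `n_seeds` independently seeded scenarios
#' and reports how often (a) the PERMANOVA period term is significant after
#' spring temperature, (b) bidirectional stepwise selection retains spring
#' temperature among elevation, year and annual temperature, and (c) the
#' socio-parasitic CWM declines significantly between periods
#' (Kruskal-Wallis), each at alpha = 0.05.
#'
#' @param n_seeds number of replicate worlds (default 100).
#' @param seed0 base seed; world `i` uses `seed0 + i`.
#' @param n_perm permutations per test (default 199).
#' @param alpha significance level.
#' @return list of rates in `[0, 1]`: `permanova_period`,
#'   `stepwise_spring`, `parasite_cwm`, plus the counts and `n_seeds`.
#' @export
recovery_rates <- function(n_seeds = 100, seed0 = 1000L, n_perm = 199,
                           alpha = 0.05) {
  hit_p <- hit_s <- hit_k <- 0L
  for (i in seq_len(n_seeds)) {
    cfg <- default_config(seed = seed0 + i)
    pool <- gen_species_pool(cfg$scenario)
    rec <- gen_units_and_records(pool, cfg$scenario)
    fr <- filter_records(rec, filter_rules(
      allowed_years = unlist(cfg$scenario$periods),
      period_exclusions = list(), periods = cfg$scenario$periods))
    units <- pool_to_units(fr, periods = cfg$scenario$periods)
    inc <- build_incidence(units, pool$registry)
    d <- sorensen_matrix(inc)
    env <- unit_environment(units, cfg)

    pt <- permanova(d, env[, c("spring_temp", "period")],
                    n_perm = n_perm, seed = cfg$seed + 11L)
    if (pt$p[2] < alpha) hit_p <- hit_p + 1L

    sel <- stepwise_select(d, env[, c("spring_temp", "mean_elev", "year",
                                      "annual_temp")],
                           n_perm = n_perm, seed = cfg$seed + 12L)
    if ("spring_temp" %in% sel$selected) hit_s <- hit_s + 1L

    tt <- merge_complex_traits(pool$traits, pool$complex$members,
                               pool$complex$label)
    tt <- tt[rownames(tt) %in% colnames(inc), , drop = FALSE]
    cw <- cwm(inc, scale_traits(tt))
    kt <- kruskal_wallis(cw$socio_parasitic, units$period)
    dir_ok <- mean(cw$socio_parasitic[units$period == "recent"]) <
      mean(cw$socio_parasitic[units$period == "historic"])
    if (kt$p < alpha && dir_ok) hit_k <- hit_k + 1L
  }
  list(permanova_period = hit_p / n_seeds,
       stepwise_spring = hit_s / n_seeds,
       parasite_cwm = hit_k / n_seeds,
       counts = c(permanova_period = hit_p, stepwise_spring = hit_s,
                  parasite_cwm = hit_k),
       n_seeds = n_seeds)
}

#' Ground truth of a scenario, for parameter-recovery assertions
#'
#' @param pool output of [gen_species_pool()].
#' @param config a [scenario_config()].
#' @return list: `warming`, `lapse`, per-period expected occupancy matrix
#'   (species x unit), expected richness per period (species with nonzero
#'   expected occupancy), expected parasite CWM share per period, and the
#'   niche table.
#' @export
ground_truth <- function(pool, config) {
  layout <- site_layout(config)
  mids <- (layout$elev_low + layout$elev_high) / 2
  response <- function(dT) exp(-dT^2 / (2 * config$niche_width^2))
  occ <- function(period) {
    Tu <- true_spring_temp(config, layout$site, mids, period)
    m <- outer(pool$niche$p_max *
                 (if (period == "recent") pool$niche$m_recent else 1),
               rep(1, length(mids))) *
      response(outer(pool$niche$t_opt, Tu, `-`))
    rownames(m) <- pool$niche$species
    m
  }
  occ_h <- occ("historic"); occ_r <- occ("recent")
  richness <- c(historic = sum(rowSums(occ_h) > 1e-12),
                recent = sum(rowSums(occ_r) > 1e-12))
  par_flag <- pool$traits$socio_parasitic
  share <- function(m) mean(colSums(m * par_flag) / colSums(m))
  list(warming = config$warming, lapse = config$lapse,
       occupancy = list(historic = occ_h, recent = occ_r),
       richness = richness,
       parasite_share = c(historic = share(occ_h), recent = share(occ_r)),
       niche = pool$niche)
}
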
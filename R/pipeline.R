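strip_classes <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[] <- lapply(x, strip_classes)
  }
  x
}

user_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("beeshift_user_error",
                                             "error", "condition")))
}

#' Default pipeline configuration
#'
#' All defaults mirror the analysis settings: 999 permutations, 95%
#' bootstrap intervals, dendrogram cut height 1.5, Ward variant `ward_d`,
#' spring = March-June, vertical gradient -6.68 K/km, elevation window
#' 1100-2899 masl, Holm multiplicity adjustment. Per-stage seeds are
#' derived deterministically from the master `seed`.
#'
#' @param seed master seed (default 1).
#' @return nested configuration list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  seed <- as.integer(seed)
  structure(list(
    seed = seed,
    scenario = scenario_config(seed = seed),
    filter = list(max_span = 500, elev_window = c(1100, 2899),
                  nest_threshold = 30),
    cluster = list(variant = "ward_d", cut_height = 1.5),
    ordination = list(candidates = c("spring_temp", "mean_elev", "year",
                                     "annual_temp"),
                      alpha_in = 0.05, alpha_out = 0.10,
                      n_perm = 999, seed = seed + 101L),
    tests = list(terms = c("spring_temp", "period"), n_perm = 999,
                 seed = seed + 202L, dispersion_center = "spatial_median",
                 adjust = "holm"),
    diversity = list(B = 200, level = 0.95, knots = 40,
                     seed = seed + 303L),
    traits = list(adjust = "holm"),
    climate = list(lapse = -6.68, splice_year = 1961,
                   periods = list(historic = 1906:1935,
                                  recent = 1991:2020),
                   indices = c("annual", "summer_half", "winter_half",
                               "spring"))),
    class = "run_config")
}

#' Read / write a pipeline configuration (JSON)
#' @param path JSON file path.
#' @return a `run_config` (read) or the path invisibly (write).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) user_error("config file not found: ", path)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- default_config(seed = if (!is.null(raw$seed)) raw$seed else 1L)
  merge_list <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(new[[nm]]))
        merge_list(base[[nm]], new[[nm]]) else new[[nm]]
    }
    base
  }
  out <- merge_list(unclass(cfg), raw)
  out$scenario <- do.call(scenario_config,
                          out$scenario[names(out$scenario) %in%
                                         names(formals(scenario_config))])
  class(out) <- "run_config"
  out
}

#' @rdname read_config
#' @param config a `run_config`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(strip_classes(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

artifact <- function(outdir, name) file.path(outdir, name)

need_artifact <- function(outdir, name, stage) {
  p <- artifact(outdir, name)
  if (!file.exists(p))
    user_error("missing upstream artifact: ", p,
               " (run stage '", stage, "' first)")
  p
}

read_incidence_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Per-unit environmental table for ordination and tests
#'
#' Builds the candidate constraint table for the synthetic world: spring
#' and annual mean temperature at each unit (lapse structure + persistent
#' site offsets + between-period warming), mean elevation, numeric year
#' and period factor. For a real-data analysis the temperatures would come
#' from the climate module's zone means instead.
#'
#' @param units sampling-unit data.frame from [pool_to_units()].
#' @param config a [default_config()]-style `run_config`.
#' @return data.frame with rownames = unit ids and columns `spring_temp`,
#'   `annual_temp`, `mean_elev`, `year`, `period`.
#' @export
unit_environment <- function(units, config) {
  per <- period_of(units$year, config$scenario$periods)
  sc <- config$scenario
  off_sp <- site_offsets(sc, "spring")[units$site]
  off_an <- site_offsets(sc, "annual")[units$site]
  data.frame(
    spring_temp = spring_temp_at(sc, units$mean_elev, per) + off_sp,
    # annual mean: same gradient but its own persistent site pattern,
    # colder base, and only part of the warming signal (warming is
    # strongest in spring) -- correlated with spring temperature but not
    # an affine transform of it
    annual_temp = sc$spring_t0 - 6 + sc$lapse * units$mean_elev / 1000 +
      0.6 * sc$warming * (per == "recent") + off_an,
    mean_elev = units$mean_elev,
    year = units$year,
    period = factor(per),
    row.names = units$id)
}

pipeline_stages <- c("simulate", "harmonize", "cluster", "ordinate",
                     "tests", "diversity", "traits", "climate")

#' Run the analysis pipeline
#'
#' Executes one stage (or `"all"`: every stage in dependency order) against
#' an output directory. Each stage writes its artifacts as plain-text
#' tables/JSON and the run manifest (`manifest.json`: config, seeds,
#' artifact checksums, package version) is updated after every stage, so
#' the pipeline can be re-entered from any completed stage.
#'
#' @param config a [default_config()]-style `run_config`.
#' @param stage one of `"simulate"`, `"harmonize"`, `"cluster"`,
#'   `"ordinate"`, `"tests"`, `"diversity"`, `"traits"`, `"climate"`,
#'   `"all"`.
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return invisibly, the accumulated result list.
#' @export
run_pipeline <- function(config = default_config(), stage = "all",
                         outdir = "beeshift_run", quiet = FALSE) {
  if (!stage %in% c(pipeline_stages, "all"))
    user_error("unknown stage '", stage, "'; expected one of: ",
               paste(c(pipeline_stages, "all"), collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stages <- if (stage == "all") pipeline_stages else stage
  say <- function(...) if (!quiet) message("[beeshift] ", ...)
  res <- list()

  for (st in stages) {
    say("stage: ", st)
    res <- switch(st,
      simulate = stage_simulate(res, config, outdir),
      harmonize = stage_harmonize(res, config, outdir),
      cluster = stage_cluster(res, config, outdir),
      ordinate = stage_ordinate(res, config, outdir),
      tests = stage_tests(res, config, outdir),
      diversity = stage_diversity(res, config, outdir),
      traits = stage_traits(res, config, outdir),
      climate = stage_climate(res, config, outdir))
    write_manifest(config, outdir)
  }
  invisible(res)
}

write_manifest <- function(config, outdir) {
  files <- sort(setdiff(list.files(outdir), "manifest.json"))
  sums <- vapply(file.path(outdir, files), function(f)
    unname(tools::md5sum(f)), "")
  cfg <- strip_classes(config)
  manifest <- list(package = "beeshift",
                   version = as.character(utils::packageVersion("beeshift")),
                   config = cfg,
                   artifacts = stats::setNames(as.list(unname(sums)), files))
  jsonlite::write_json(manifest, artifact(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

stage_simulate <- function(res, config, outdir) {
  pool <- gen_species_pool(config$scenario)
  records <- gen_units_and_records(pool, config$scenario)
  utils::write.csv(records, artifact(outdir, "records.csv"),
                   row.names = FALSE)
  utils::write.csv(pool$traits, artifact(outdir, "traits.csv"),
                   row.names = FALSE)
  res$pool <- pool
  res$records <- records
  res
}

load_pool <- function(res, config) {
  if (is.null(res$pool)) res$pool <- gen_species_pool(config$scenario)
  res
}

stage_harmonize <- function(res, config, outdir) {
  res <- load_pool(res, config)
  if (is.null(res$records)) {
    p <- need_artifact(outdir, "records.csv", "simulate")
    res$records <- read_records(p)
  }
  rules <- filter_rules(max_span = config$filter$max_span,
                        elev_window = config$filter$elev_window,
                        nest_threshold = config$filter$nest_threshold,
                        allowed_years = unlist(config$scenario$periods),
                        period_exclusions = list(),
                        periods = config$scenario$periods)
  filtered <- filter_records(res$records, rules)
  units <- pool_to_units(filtered, periods = config$scenario$periods)
  incidence <- build_incidence(units, res$pool$registry)
  write_harmonized(units, incidence, artifact(outdir, "units.csv"),
                   artifact(outdir, "incidence.csv"))
  res$units <- units
  res$incidence <- incidence
  res
}

load_harmonized <- function(res, config, outdir) {
  res <- load_pool(res, config)
  if (is.null(res$incidence)) {
    up <- need_artifact(outdir, "units.csv", "harmonize")
    ip <- need_artifact(outdir, "incidence.csv", "harmonize")
    res$units <- utils::read.csv(up, stringsAsFactors = FALSE)
    rownames(res$units) <- res$units$id
    res$incidence <- read_incidence_csv(ip)
  }
  res
}

stage_cluster <- function(res, config, outdir) {
  res <- load_harmonized(res, config, outdir)
  d <- sorensen_matrix(res$incidence)
  hc <- ward_cluster(d, config$cluster$variant)
  labels <- cut_tree(hc, config$cluster$cut_height)
  groups <- cross_with_period(labels, res$units,
                              periods = config$scenario$periods)
  utils::write.csv(as.matrix(d), artifact(outdir, "sorensen.csv"))
  dendrogram_newick(hc, artifact(outdir, "dendrogram.nwk"))
  utils::write.csv(groups, artifact(outdir, "cluster_groups.csv"),
                   row.names = FALSE)
  utils::write.csv(attr(groups, "summary"),
                   artifact(outdir, "cluster_summary.csv"),
                   row.names = FALSE)
  res$dissim <- d
  res$groups <- groups
  res
}

load_groups <- function(res, config, outdir) {
  res <- load_harmonized(res, config, outdir)
  if (is.null(res$groups)) {
    gp <- need_artifact(outdir, "cluster_groups.csv", "cluster")
    res$groups <- utils::read.csv(gp, stringsAsFactors = FALSE)
    res$dissim <- sorensen_matrix(res$incidence)
  }
  res
}

stage_ordinate <- function(res, config, outdir) {
  res <- load_groups(res, config, outdir)
  env <- unit_environment(res$units, config)
  cand <- env[, intersect(config$ordination$candidates, names(env)),
              drop = FALSE]
  sel <- stepwise_select(res$dissim, cand,
                         alpha_in = config$ordination$alpha_in,
                         alpha_out = config$ordination$alpha_out,
                         n_perm = config$ordination$n_perm,
                         seed = config$ordination$seed,
                         incidence = res$incidence)
  anova_tab <- if (sel$m > 0)
    permutation_anova(sel, cand[, sel$selected, drop = FALSE],
                      n_perm = config$ordination$n_perm,
                      seed = config$ordination$seed, by = "model")
  else NULL
  r2 <- if (sel$m > 0) adjusted_r2(sel) else
    list(r_squared = 0, adj_r_squared = 0)
  vec <- fit_vectors(sel, env[, c("spring_temp", "mean_elev", "year")],
                     n_perm = config$ordination$n_perm,
                     seed = config$ordination$seed)
  utils::write.csv(sel$unit_scores, artifact(outdir, "unit_scores.csv"))
  if (!is.null(sel$species_scores))
    utils::write.csv(sel$species_scores,
                     artifact(outdir, "species_scores.csv"))
  utils::write.csv(sel$trace, artifact(outdir, "selection_trace.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(
    selected = sel$selected,
    n = sel$n,
    eigenvalues = sel$eigenvalues,
    constrained_inertia = sel$constrained_inertia,
    total_inertia = sel$total_inertia,
    r_squared = r2$r_squared, adj_r_squared = r2$adj_r_squared,
    anova = anova_tab,
    vectors = vec,
    n_perm = config$ordination$n_perm, seed = config$ordination$seed),
    artifact(outdir, "ordination.json"), auto_unbox = TRUE, digits = NA)
  res$cap <- sel
  res
}

stage_tests <- function(res, config, outdir) {
  res <- load_groups(res, config, outdir)
  env <- unit_environment(res$units, config)
  terms <- env[, config$tests$terms, drop = FALSE]
  pt <- permanova(res$dissim, terms, n_perm = config$tests$n_perm,
                  seed = config$tests$seed)
  grp <- res$groups$group[match(rownames(as.matrix(res$dissim)),
                                res$groups$id)]
  bd <- beta_dispersion(res$dissim, grp,
                        center = config$tests$dispersion_center)
  utils::write.csv(pt, artifact(outdir, "permanova.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    permanova = pt, n_perm = config$tests$n_perm, seed = config$tests$seed,
    n = attr(pt, "n"),
    dispersion = list(f = bd$f, df = bd$df, p = bd$p,
                      group_means = as.list(bd$group_means))),
    artifact(outdir, "community_tests.json"), auto_unbox = TRUE,
    digits = NA)
  res$permanova <- pt
  res$dispersion <- bd
  res
}

stage_diversity <- function(res, config, outdir) {
  res <- load_groups(res, config, outdir)
  groups <- split(seq_len(nrow(res$incidence)),
                  res$groups$group[match(rownames(res$incidence),
                                         res$groups$id)])
  mats <- lapply(groups, function(i) res$incidence[i, , drop = FALSE])
  curves <- list()
  covs <- list()
  for (g in names(mats)) {
    f <- incidence_freqs(mats[[g]])
    tg <- size_grid(f$T, knots = config$diversity$knots)
    for (q in 0:2) {
      ci <- bootstrap_ci(f, q, t_grid = tg, B = config$diversity$B,
                         level = config$diversity$level,
                         seed = config$diversity$seed)
      ci$group <- g
      curves[[length(curves) + 1]] <- ci
    }
    cc <- coverage_curve(f, tg)
    cc$group <- g
    covs[[length(covs) + 1]] <- cc
  }
  est <- estimate_at_common_size(mats, B = config$diversity$B,
                                 level = config$diversity$level,
                                 seed = config$diversity$seed)
  utils::write.csv(do.call(rbind, curves),
                   artifact(outdir, "diversity_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, covs),
                   artifact(outdir, "coverage_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(est, artifact(outdir, "diversity_estimates.csv"),
                   row.names = FALSE)
  res$diversity <- est
  res
}

stage_traits <- function(res, config, outdir) {
  res <- load_groups(res, config, outdir)
  if (is.null(res$pool$traits)) user_error("missing trait table")
  tt <- merge_complex_traits(res$pool$traits,
                             res$pool$complex$members,
                             res$pool$complex$label)
  tt <- tt[rownames(tt) %in% colnames(res$incidence), , drop = FALSE]
  sc <- scale_traits(tt)
  cw <- cwm(res$incidence, sc)
  groups <- res$groups
  both <- vapply(split(groups$period, groups$cluster),
                 function(p) length(unique(p)) > 1, TRUE)
  if (!any(both)) {
    # strong period turnover can make every cluster period-pure; fall back
    # to one overall between-period comparison
    warning("no elevation cluster contains both periods; ",
            "comparing periods over all units")
    groups$cluster <- "all"
  }
  cmp <- compare_traits(cw, groups, adjust_method = config$traits$adjust)
  utils::write.csv(cw, artifact(outdir, "cwm.csv"))
  utils::write.csv(cmp, artifact(outdir, "trait_tests.csv"),
                   row.names = FALSE)
  res$cwm <- cw
  res$trait_tests <- cmp
  res
}

stage_climate <- function(res, config, outdir) {
  cl <- gen_climate(config$scenario)
  wts <- regrid_weights(cl$coarse, cl$fine, "patch_like")
  coarse_on_fine <- regrid(cl$coarse, cl$fine, weights = wts)
  overlap <- intersect(cl$coarse$years, cl$fine$years)
  overlap <- overlap[overlap < config$climate$splice_year + 30 &
                       overlap >= config$climate$splice_year]
  bias <- fit_bias(coarse_on_fine, cl$fine, overlap)
  fused <- apply_bias(coarse_on_fine, cl$fine, bias,
                      splice_year = config$climate$splice_year)
  dem_wts <- regrid_weights(cl$fine, cl$dem, "patch_like")
  zones <- list(c(1100, 1699), c(1700, 2299), c(2300, 2899))
  zone_tab <- list()
  shifts <- list()
  for (idx in config$climate$indices) {
    for (p in names(config$climate$periods)) {
      fld <- temperature_index(fused, idx, config$climate$periods[[p]])
      fld$elev <- cl$fine$elev
      down <- downscale(fld, cl$dem, lapse = config$climate$lapse,
                        weights = dem_wts)
      write_ascii_grid(down, artifact(outdir,
                                      paste0("index_", idx, "_", p, ".asc")))
      zm <- zone_means(down, cl$dem, zones)
      zone_tab[[length(zone_tab) + 1]] <- data.frame(
        index = idx, period = p, zone = names(zm), mean_temp = unname(zm))
      if (idx == "spring") shifts[[p]] <- mean(down$z)
    }
  }
  warming <- shifts$recent - shifts$historic
  utils::write.csv(do.call(rbind, zone_tab),
                   artifact(outdir, "zone_means.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    spring_warming_K = warming,
    equivalent_shift_m = equivalent_shift(warming, config$climate$lapse),
    shift_m_per_K = equivalent_shift(1, config$climate$lapse),
    lapse = config$climate$lapse),
    artifact(outdir, "climate_summary.json"), auto_unbox = TRUE,
    digits = NA)
  res$climate <- list(warming = warming, bias = bias)
  res
}
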
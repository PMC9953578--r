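#' Species registry
#'
#' A registry maps every species string that can appear in the occurrence
#' data to a canonical name: directly, through a synonym, or through
#' membership in a species complex (e.g. the *B. lucorum/cryptarum* complex,
#' whose members cannot be separated in historical material). Strings listed
#' in `drop` are recognized but intentionally removed (e.g. "B. sp.",
#' specimens not identified to species level).
#'
#' @param canonical character vector of canonical species names.
#' @param synonyms named character vector: `names()` are old names, values
#'   are the canonical names they map to.
#' @param complexes named list: each element is a character vector of member
#'   species, the element name is the complex label (itself a canonical
#'   community-matrix name).
#' @param parasites character vector of canonical names (or complex labels)
#'   flagged as socio-parasitic (cuckoo) species.
#' @param drop character vector of strings to be silently excluded.
#' @return An object of class `species_registry`.
#' @export
species_registry <- function(canonical, synonyms = character(),
                             complexes = list(), parasites = character(),
                             drop = character()) {
  stopifnot(is.character(canonical), !anyDuplicated(canonical))
  if (length(synonyms) && is.null(names(synonyms)))
    stop("`synonyms` must be a named character vector (old name -> canonical)")
  members <- unlist(complexes, use.names = FALSE)
  if (anyDuplicated(members))
    stop("a species cannot belong to two complexes")
  if (!all(names(complexes) %in% canonical))
    stop("complex labels must be canonical names")
  structure(list(canonical = canonical, synonyms = synonyms,
                 complexes = complexes, parasites = parasites, drop = drop),
            class = "species_registry")
}

#' @export
print.species_registry <- function(x, ...) {
  cat("<species_registry>\n",
      length(x$canonical), "canonical names;",
      length(x$synonyms), "synonyms;",
      length(x$complexes), "complexes;",
      length(x$parasites), "parasites flagged\n")
  invisible(x)
}

#' Normalize species names against a registry
#'
#' Resolves synonyms, collapses complex members onto their complex label and
#' rejects unknown strings. Strings on the registry's drop list return `NA`
#' so callers can discard those records while still distinguishing them from
#' genuinely unknown names, which are an error.
#'
#' @param name character vector of raw species strings.
#' @param registry a [species_registry()].
#' @return character vector of canonical names; `NA` for dropped strings.
#' @export
normalize_species <- function(name, registry) {
  stopifnot(inherits(registry, "species_registry"))
  syn <- registry$synonyms
  res <- ifelse(name %in% names(syn), unname(syn[match(name, names(syn))]), name)
  # complex membership applies after synonym resolution
  for (label in names(registry$complexes)) {
    res[res %in% registry$complexes[[label]]] <- label
  }
  res[name %in% registry$drop | res %in% registry$drop] <- NA_character_
  known <- is.na(res) | res %in% registry$canonical |
    res %in% names(registry$complexes)
  if (any(!known))
    stop("unknown species name(s): ",
         paste(unique(name[!known]), collapse = ", "))
  res
}

#' Filtering rules for occurrence records
#'
#' Encodes the harmonization rules applied to the raw records before
#' pooling: maximum uncertainty of the elevation assignment, a required
#' recording date, the elevational study window, the allowed survey years,
#' period-scoped species exclusions, and a heuristic removing suspected
#' single nest excavations (one species at a location-date in unusually high
#' numbers).
#'
#' @param max_span maximum elevation uncertainty in meters; records whose
#'   interval spans strictly more than this are excluded (default 500 m,
#'   a span of exactly 500 m is kept).
#' @param elev_window numeric length 2, inclusive elevation window in masl.
#' @param allowed_years integer vector of survey years retained.
#' @param require_date logical; drop records without a calendar date.
#' @param nest_threshold minimum total count for the nest-excavation
#'   heuristic: a (site, date, elevation interval) group with exactly one
#'   species and a total count at or above this is excluded.
#' @param period_exclusions named list: name is a period label, value a
#'   character vector of canonical species excluded for that period.
#' @param periods named list mapping period label to the years it contains.
#' @return An object of class `filter_rules`.
#' @export
filter_rules <- function(max_span = 500,
                         elev_window = c(1100, 2899),
                         allowed_years = c(1935L, 1936L, 2020L),
                         require_date = TRUE,
                         nest_threshold = 30,
                         period_exclusions = list(
                           historic = c("B. mesomelas", "B. campestris")),
                         periods = list(historic = c(1935L, 1936L),
                                        recent = 2020L)) {
  structure(list(max_span = max_span, elev_window = elev_window,
                 allowed_years = as.integer(allowed_years),
                 require_date = require_date,
                 nest_threshold = nest_threshold,
                 period_exclusions = period_exclusions,
                 periods = periods),
            class = "filter_rules")
}

period_of <- function(year, periods) {
  out <- rep(NA_character_, length(year))
  for (p in names(periods)) out[year %in% periods[[p]]] <- p
  out
}

#' Read occurrence records from CSV
#'
#' Expected columns: `species,count,site,year,month,day,elev_low,elev_high`
#' (header required, missing values empty). A record with a point elevation
#' may leave `elev_high` empty; it is treated as the degenerate interval
#' `[elev_low, elev_low]`.
#'
#' @param path CSV file path.
#' @return data.frame of occurrence records.
#' @export
read_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "count", "site", "year", "month", "day",
            "elev_low", "elev_high")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("records CSV missing column(s): ", paste(miss, collapse = ", "))
  as_records(df)
}

#' Validate and normalize a raw record table
#'
#' @param df data.frame with the record CSV columns.
#' @return validated data.frame with `elev_high` filled for point records.
#' @export
as_records <- function(df) {
  df$year <- as.integer(df$year)
  df$count <- suppressWarnings(as.integer(df$count))
  df$elev_low <- as.numeric(df$elev_low)
  df$elev_high <- as.numeric(df$elev_high)
  df$elev_high[is.na(df$elev_high)] <- df$elev_low[is.na(df$elev_high)]
  bad <- !is.na(df$elev_low) & df$elev_low > df$elev_high
  if (any(bad)) stop(sum(bad), " record(s) with elev_low > elev_high")
  df
}

#' Filter occurrence records
#'
#' Applies all rules in [filter_rules()] and attaches a per-rule exclusion
#' log as attribute `"exclusion_log"` (named integer vector). Filtering is
#' idempotent.
#'
#' @param records data.frame from [read_records()] / [as_records()].
#' @param rules a [filter_rules()] object.
#' @return the surviving records, with the exclusion log attached.
#' @export
filter_records <- function(records, rules = filter_rules()) {
  stopifnot(inherits(rules, "filter_rules"))
  df <- as_records(records)
  log <- c(year = 0L, no_date = 0L, elev_span = 0L, elev_window = 0L,
           species_period = 0L, nest_excavation = 0L)

  keep <- df$year %in% rules$allowed_years
  log["year"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  if (rules$require_date) {
    keep <- !is.na(df$month) & !is.na(df$day)
    log["no_date"] <- sum(!keep)
    df <- df[keep, , drop = FALSE]
  }

  keep <- (df$elev_high - df$elev_low) <= rules$max_span
  log["elev_span"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  keep <- df$elev_low >= rules$elev_window[1] &
    df$elev_high <= rules$elev_window[2]
  log["elev_window"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  per <- period_of(df$year, rules$periods)
  keep <- rep(TRUE, nrow(df))
  for (p in names(rules$period_exclusions)) {
    keep <- keep & !(per == p & df$species %in% rules$period_exclusions[[p]])
  }
  log["species_period"] <- sum(!keep)
  df <- df[keep, , drop = FALSE]

  if (nrow(df)) {
    grp <- paste(df$site, df$year, df$month, df$day,
                 df$elev_low, df$elev_high, sep = "\r")
    n_species <- tapply(df$species, grp, function(s) length(unique(s)))
    tot <- tapply(ifelse(is.na(df$count), 0L, df$count), grp, sum)
    nest <- names(n_species)[n_species == 1L & tot >= rules$nest_threshold]
    keep <- !(grp %in% nest)
    log["nest_excavation"] <- sum(!keep)
    df <- df[keep, , drop = FALSE]
  }

  rownames(df) <- NULL
  attr(df, "exclusion_log") <- log
  df
}

merge_intervals <- function(low, high) {
  # union of closed intervals; returns merged intervals sorted by low
  o <- order(low, high)
  low <- low[o]; high <- high[o]
  ml <- low[1]; mh <- high[1]
  outl <- numeric(0); outh <- numeric(0)
  for (i in seq_along(low)[-1]) {
    if (low[i] <= mh) {
      mh <- max(mh, high[i])
    } else {
      outl <- c(outl, ml); outh <- c(outh, mh)
      ml <- low[i]; mh <- high[i]
    }
  }
  cbind(low = c(outl, ml), high = c(outh, mh))
}

unit_id <- function(year, site, mean_elev) {
  sprintf("%d#%s#%dMSL", year, site, as.integer(round(mean_elev)))
}

#' Pool filtered records into sampling units
#'
#' Historical records are pooled per (year, site, elevation interval);
#' overlapping (redundant) intervals of one site and year are merged into
#' their union. Recent records are re-binned into the elevation intervals
#' present in the historical data of the same site (midpoint-in-interval,
#' ties going to the lower bin) so that both periods share the coarse
#' historical elevation structure. Recent records at a site with no
#' historical interval, or whose midpoint falls outside every historical
#' interval, are dropped and logged.
#'
#' @param records filtered record data.frame.
#' @param periods named list mapping period label to years; the first
#'   element is taken as the historical (bin-defining) period.
#' @return data.frame of sampling units (one row each: `id`, `year`, `site`,
#'   `elev_low`, `elev_high`, `mean_elev`, `period`, `n_species`) with a
#'   list-column `species`; dropped-record count in attribute
#'   `"dropped_recent"`, per-cell record provenance in attribute
#'   `"provenance"`.
#' @export
pool_to_units <- function(records,
                          periods = list(historic = c(1935L, 1936L),
                                         recent = 2020L)) {
  df <- as_records(records)
  df$period <- period_of(df$year, periods)
  if (anyNA(df$period))
    stop("record year(s) outside declared periods: ",
         paste(unique(df$year[is.na(df$period)]), collapse = ", "))
  hist_label <- names(periods)[1]

  hist <- df[df$period == hist_label, , drop = FALSE]
  rec <- df[df$period != hist_label, , drop = FALSE]
  if (!nrow(hist)) stop("no records in the historical (bin-defining) period")

  units <- list()
  add_unit <- function(year, site, low, high, rows) {
    key <- unit_id(year, site, (low + high) / 2)
    if (is.null(units[[key]])) {
      units[[key]] <<- list(year = year, site = site, low = low, high = high,
                            rows = rows)
    } else {
      units[[key]]$rows <<- c(units[[key]]$rows, rows)
    }
  }

  # historical units: merge overlapping intervals within (year, site)
  bins <- list()  # per site: matrix of merged historical intervals
  for (site in unique(hist$site)) {
    hs <- hist[hist$site == site, , drop = FALSE]
    for (year in unique(hs$year)) {
      hy <- hs[hs$year == year, , drop = FALSE]
      merged <- merge_intervals(hy$elev_low, hy$elev_high)
      for (k in seq_len(nrow(merged))) {
        lo <- merged[k, "low"]; hi <- merged[k, "high"]
        in_bin <- hy$elev_low >= lo & hy$elev_high <= hi
        add_unit(year, site, lo, hi, rownames(hy)[in_bin])
      }
    }
    bins[[site]] <- merge_intervals(hs$elev_low, hs$elev_high)
  }

  # recent units: assign to historical bins of the same site by midpoint
  dropped <- 0L
  if (nrow(rec)) for (i in seq_len(nrow(rec))) {
    site <- rec$site[i]
    b <- bins[[site]]
    if (is.null(b)) { dropped <- dropped + 1L; next }
    mid <- (rec$elev_low[i] + rec$elev_high[i]) / 2
    hit <- which(b[, "low"] <= mid & mid <= b[, "high"])
    if (!length(hit)) { dropped <- dropped + 1L; next }
    k <- hit[which.min(b[hit, "low"])]  # tie -> lower bin
    add_unit(rec$year[i], site, b[k, "low"], b[k, "high"], rownames(rec)[i])
  }

  out <- do.call(rbind, lapply(names(units), function(key) {
    u <- units[[key]]
    data.frame(id = key, year = u$year, site = u$site,
               elev_low = u$low, elev_high = u$high,
               mean_elev = (u$low + u$high) / 2,
               stringsAsFactors = FALSE)
  }))
  out$period <- period_of(out$year, periods)
  out$species <- lapply(names(units), function(key) {
    sort(unique(df[units[[key]]$rows, "species"]))
  })
  out$n_species <- vapply(out$species, length, integer(1))
  out <- out[order(out$year, out$site, out$mean_elev), , drop = FALSE]
  rownames(out) <- out$id
  attr(out, "dropped_recent") <- dropped
  attr(out, "provenance") <- lapply(units, `[[`, "rows")[out$id]
  out
}

#' Build a binary incidence matrix from sampling units
#'
#' Rows are sampling units, columns canonical species, entries 1 if the
#' species occurs in the unit. Species columns with zero total incidence are
#' removed; all-zero unit rows are retained with a warning.
#'
#' @param units data.frame from [pool_to_units()].
#' @param registry optional [species_registry()]; when given, species names
#'   are normalized (and drop-listed names removed) before construction.
#' @return integer matrix with unit ids as rownames, species as colnames.
#' @export
build_incidence <- function(units, registry = NULL) {
  stopifnot(nrow(units) >= 1)
  sp_sets <- units$species
  if (!is.null(registry)) {
    sp_sets <- lapply(sp_sets, function(s) {
      v <- normalize_species(s, registry)
      sort(unique(v[!is.na(v)]))
    })
  }
  species <- sort(unique(unlist(sp_sets)))
  mat <- matrix(0L, nrow = nrow(units), ncol = length(species),
                dimnames = list(units$id, species))
  for (i in seq_len(nrow(units))) mat[i, sp_sets[[i]]] <- 1L
  empty <- rowSums(mat) == 0
  if (any(empty))
    warning(sum(empty), " sampling unit(s) with no species retained as ",
            "all-zero rows: ", paste(units$id[empty], collapse = ", "))
  mat[, colSums(mat) > 0, drop = FALSE]
}

#' Write sampling units and incidence matrix to CSV
#'
#' @param units data.frame from [pool_to_units()].
#' @param incidence matrix from [build_incidence()].
#' @param units_path,incidence_path output CSV paths.
#' @return invisibly, the two paths.
#' @export
write_harmonized <- function(units, incidence, units_path, incidence_path) {
  utils::write.csv(units[, c("id", "year", "site", "elev_low", "elev_high",
                             "mean_elev", "n_species")],
                   units_path, row.names = FALSE)
  df <- data.frame(unit = rownames(incidence), incidence,
                   check.names = FALSE)
  utils::write.csv(df, incidence_path, row.names = FALSE)
  invisible(c(units_path, incidence_path))
}
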
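#' Canonical trait column names
#'
#' The twelve traits used throughout: worker proboscis length (mm), worker
#' body size (mm), above/belowground nesting indicators, social parasitism,
#' habitat preference indicators (open, forest/edge), species temperature
#' index (STI, degrees C), micro- and macroclimatic preference indicators.
#' @export
trait_columns <- function() {
  c("proboscis_length", "body_size", "nest_above", "nest_below",
    "socio_parasitic", "habitat_open", "habitat_forest_edge", "STI",
    "micro_wide", "micro_cold", "macro_indiscriminate", "macro_alpine")
}

#' Read a species trait table from CSV
#'
#' Schema: a `species` column plus the twelve [trait_columns()].
#'
#' @param path CSV path.
#' @return data.frame with species as rownames.
#' @export
read_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  miss <- setdiff(c("species", trait_columns()), names(df))
  if (length(miss))
    stop("trait CSV missing column(s): ", paste(miss, collapse = ", "))
  rownames(df) <- df$species
  df[, c("species", trait_columns())]
}

#' Merge complex members into a single averaged trait row
#'
#' Species that cannot be separated in the historical material (e.g. the
#' *B. lucorum/cryptarum* complex) enter the analysis as one taxon whose
#' trait values are the arithmetic mean of the members; binary traits may
#' become fractional.
#'
#' @param table trait data.frame (species rownames).
#' @param members character vector of member species to merge.
#' @param label name of the resulting complex row.
#' @return trait table with member rows replaced by the complex row.
#' @export
merge_complex_traits <- function(table, members, label) {
  miss <- setdiff(members, rownames(table))
  if (length(miss))
    stop("complex member(s) missing from trait table: ",
         paste(miss, collapse = ", "))
  tc <- intersect(trait_columns(), names(table))
  merged <- colMeans(table[members, tc, drop = FALSE])
  out <- table[!(rownames(table) %in% members), , drop = FALSE]
  row <- out[0, ][1, ]  # template row
  row[tc] <- as.list(merged)
  row$species <- label
  rownames(row) <- label
  out <- rbind(out, row)
  out
}

#' Center and scale trait values
#'
#' Each trait column is centered to mean zero and divided by its sample
#' standard deviation across the species pool. Constant columns are
#' centered only (all zeros) with a warning. Idempotent on already-scaled
#' data.
#'
#' @param table trait data.frame.
#' @return the table with scaled trait columns; original means and sds in
#'   attributes `"center"` and `"scale"`.
#' @export
scale_traits <- function(table) {
  if (nrow(table) < 2) stop("need at least 2 species to scale")
  tc <- intersect(trait_columns(), names(table))
  ctr <- vapply(table[tc], mean, 0)
  sdv <- vapply(table[tc], stats::sd, 0)
  const <- sdv == 0
  if (any(const)) {
    warning("constant trait column(s) centered only: ",
            paste(tc[const], collapse = ", "))
    sdv[const] <- 1
  }
  for (j in seq_along(tc))
    table[[tc[j]]] <- (table[[tc[j]]] - ctr[j]) / sdv[j]
  attr(table, "center") <- ctr
  attr(table, "scale") <- sdv
  table
}

#' Community-weighted means of traits per sampling unit
#'
#' With a presence/absence matrix all present species carry equal weight,
#' so the CWM of a trait in a unit is the mean trait value over the species
#' present. Units without species yield a missing row with a warning.
#'
#' @param incidence binary units-by-species matrix.
#' @param traits trait data.frame (scaled or raw), species rownames
#'   covering every incidence column.
#' @return data.frame units x traits of CWM values.
#' @export
cwm <- function(incidence, traits) {
  m <- as.matrix(incidence)
  miss <- setdiff(colnames(m), rownames(traits))
  if (length(miss))
    stop("species without trait rows: ", paste(miss, collapse = ", "))
  tc <- intersect(trait_columns(), names(traits))
  Tm <- as.matrix(traits[colnames(m), tc, drop = FALSE])
  rich <- rowSums(m)
  if (any(rich == 0))
    warning(sum(rich == 0), " unit(s) with no species: CWM set to NA")
  out <- (m %*% Tm) / rich    # NaN/Inf-safe: rich 0 -> Inf -> fixed below
  out[rich == 0, ] <- NA_real_
  as.data.frame(out)
}

#' Compare trait CWM distributions between periods within clusters
#'
#' For each trait and each elevation cluster, a Kruskal-Wallis rank sum
#' test of the CWM values between sampling periods; p-values are
#' multiplicity-adjusted across the whole family of tests. Clusters missing
#' one period are skipped and logged.
#'
#' @param cwm_table data.frame from [cwm()] (unit rownames).
#' @param cluster_groups data.frame from [cross_with_period()] (`id`,
#'   `cluster`, `period`).
#' @param adjust_method multiplicity adjustment (see [adjust_pvalues()]).
#' @return data.frame: `trait`, `cluster`, `h`, `df`, `p`, `p_adj`;
#'   skipped combinations in attribute `"skipped"`.
#' @export
compare_traits <- function(cwm_table, cluster_groups,
                           adjust_method = "holm") {
  cg <- cluster_groups[match(rownames(cwm_table), cluster_groups$id), ]
  stopifnot(!anyNA(cg$id))
  rows <- list()
  skipped <- character(0)
  for (cl in sort(unique(cg$cluster))) {
    idx <- which(cg$cluster == cl)
    pers <- unique(cg$period[idx])
    if (length(pers) < 2) {
      skipped <- c(skipped, cl)
      next
    }
    for (tr in names(cwm_table)) {
      v <- cwm_table[idx, tr]
      ok <- !is.na(v)
      kt <- kruskal_wallis(v[ok], cg$period[idx][ok])
      rows[[length(rows) + 1]] <- data.frame(
        trait = tr, cluster = cl, h = kt$h, df = kt$df, p = kt$p)
    }
  }
  if (!length(rows)) stop("no cluster has units from both periods")
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p, adjust_method)
  attr(out, "skipped") <- skipped
  out
}
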
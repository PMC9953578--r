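#' Grid and monthly-temperature containers
#'
#' Internal raster-like containers: a grid is north-up and cell-center
#' registered, stored as a matrix with rows indexed by `y` and columns by
#' `x`. A monthly grid stacks mean temperatures as a 4-D array
#' `[y, x, month, year]`.
#'
#' @param x,y cell-center coordinate vectors (regular spacing).
#' @param values array `[length(y), length(x), 12, length(years)]`.
#' @param years integer vector of calendar years covered.
#' @param elev optional elevation matrix `[y, x]` in meters.
#' @return object of class `monthly_grid`.
#' @export
monthly_grid <- function(x, y, values, years, elev = NULL) {
  stopifnot(length(dim(values)) == 4,
            dim(values)[1] == length(y), dim(values)[2] == length(x),
            dim(values)[3] == 12, dim(values)[4] == length(years))
  if (length(x) > 2 && stats::sd(diff(x)) > 1e-8 * abs(mean(diff(x))))
    stop("x spacing not regular")
  if (length(y) > 2 && stats::sd(diff(y)) > 1e-8 * abs(mean(diff(y))))
    stop("y spacing not regular")
  if (anyNA(values)) stop("NaN/NA inside the declared domain")
  structure(list(x = x, y = y, values = values, years = as.integer(years),
                 elev = elev),
            class = "monthly_grid")
}

#' A single raster field
#' @param x,y cell-center coordinates.
#' @param z matrix `[length(y), length(x)]`.
#' @return object of class `raster_field`.
#' @export
raster_field <- function(x, y, z) {
  stopifnot(nrow(z) == length(y), ncol(z) == length(x))
  structure(list(x = x, y = y, z = z), class = "raster_field")
}

#' Read / write ESRI ASCII grids
#'
#' Minimal plain-text raster interchange (`.asc`): header rows `ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value` followed by
#' the matrix north-to-south.
#'
#' @param path file path.
#' @return a `raster_field` (read) or the path invisibly (write).
#' @export
read_ascii_grid <- function(path) {
  ln <- readLines(path, n = 6)
  kv <- do.call(rbind, strsplit(trimws(ln), "\\s+"))
  hdr <- stats::setNames(as.numeric(kv[, 2]), tolower(kv[, 1]))
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  nc <- hdr["ncols"]; nr <- hdr["nrows"]; cs <- hdr["cellsize"]
  stopifnot(nrow(m) == nr, ncol(m) == nc)
  m[m == hdr["nodata_value"]] <- NA
  x <- hdr["xllcorner"] + cs * (seq_len(nc) - 0.5)
  y <- hdr["yllcorner"] + cs * (nr - seq_len(nr) + 0.5)  # row 1 = north
  raster_field(unname(x), unname(y), m)
}

#' @rdname read_ascii_grid
#' @param field a `raster_field` to write.
#' @export
write_ascii_grid <- function(field, path) {
  cs <- if (length(field$x) > 1) diff(field$x)[1] else 1
  hdr <- c(sprintf("ncols %d", length(field$x)),
           sprintf("nrows %d", length(field$y)),
           sprintf("xllcorner %.10g", min(field$x) - cs / 2),
           sprintf("yllcorner %.10g", min(field$y) - cs / 2),
           sprintf("cellsize %.10g", cs),
           "NODATA_value -9999")
  z <- field$z
  z[is.na(z)] <- -9999
  # ensure row 1 is the northernmost row
  if (length(field$y) > 1 && field$y[1] < field$y[length(field$y)])
    z <- z[rev(seq_len(nrow(z))), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(z, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# moving-least-squares interpolation weights: for each target point, fit a
# local biquadratic by inverse-distance-weighted least squares over the k
# nearest source cells; the prediction is linear in the data, so a sparse
# weight matrix (targets x sources) is precomputed once per grid pair.
mls_weights <- function(sx, sy, tx, ty, k = 12) {
  src <- cbind(rep(sx, each = length(sy)), rep(sy, times = length(sx)))
  ns <- nrow(src)
  k <- min(k, ns)
  tgt <- cbind(rep(tx, each = length(ty)), rep(ty, times = length(tx)))
  W <- matrix(0, nrow(tgt), ns)
  scale_d <- max(diff(range(sx)), diff(range(sy)), 1)
  for (i in seq_len(nrow(tgt))) {
    d2 <- (src[, 1] - tgt[i, 1])^2 + (src[, 2] - tgt[i, 2])^2
    nn <- order(d2)[seq_len(k)]
    dx <- (src[nn, 1] - tgt[i, 1]) / scale_d
    dy <- (src[nn, 2] - tgt[i, 2]) / scale_d
    X <- cbind(1, dx, dy, dx^2, dx * dy, dy^2)
    w <- 1 / (d2[nn] / scale_d^2 + 1e-10)
    XtW <- t(X * w)
    coefw <- tryCatch(solve(XtW %*% X, XtW),
                      error = function(e) {
                        # degenerate geometry: fall back to linear patch
                        Xl <- X[, 1:3, drop = FALSE]
                        XtWl <- t(Xl * w)
                        solve(XtWl %*% Xl, XtWl)
                      })
    W[i, nn] <- coefw[1, ]  # value at the target = intercept of local fit
  }
  W
}

bilinear_weights <- function(sx, sy, tx, ty) {
  ns <- length(sx) * length(sy)
  tgt <- cbind(rep(tx, each = length(ty)), rep(ty, times = length(tx)))
  W <- matrix(0, nrow(tgt), ns)
  cell <- function(ix, iy) (ix - 1) * length(sy) + iy
  for (i in seq_len(nrow(tgt))) {
    px <- min(max(tgt[i, 1], min(sx)), max(sx))  # clamp to domain
    py <- min(max(tgt[i, 2], min(sy)), max(sy))
    ix <- findInterval(px, sx, all.inside = TRUE)
    iy <- findInterval(py, sy, all.inside = TRUE)
    fx <- if (sx[ix + 1] > sx[ix]) (px - sx[ix]) / (sx[ix + 1] - sx[ix]) else 0
    fy <- if (sy[iy + 1] > sy[iy]) (py - sy[iy]) / (sy[iy + 1] - sy[iy]) else 0
    W[i, cell(ix, iy)] <- (1 - fx) * (1 - fy)
    W[i, cell(ix + 1, iy)] <- fx * (1 - fy)
    W[i, cell(ix, iy + 1)] <- (1 - fx) * fy
    W[i, cell(ix + 1, iy + 1)] <- fx * fy
  }
  W
}

#' Precompute regridding weights between two grids
#'
#' `patch_like` (default) uses local biquadratic least-squares patches with
#' inverse-distance weights (a moving-least-squares scheme in the spirit of
#' higher-order patch recovery); `bilinear` is standard bilinear
#' interpolation with edge clamping. Both reproduce constant fields
#' exactly; both are exact on linear fields at interior targets.
#'
#' @param src,target grids: lists/objects with `x` and `y`.
#' @param method `"patch_like"` or `"bilinear"`.
#' @return a `regrid_weights` object.
#' @export
regrid_weights <- function(src, target, method = c("patch_like", "bilinear")) {
  method <- match.arg(method)
  if (method == "patch_like" &&
      (max(target$x) > max(src$x) || min(target$x) < min(src$x) ||
       max(target$y) > max(src$y) || min(target$y) < min(src$y)))
    warning("target extends beyond source domain: edge targets use the ",
            "nearest patches")
  W <- if (method == "patch_like")
    mls_weights(src$x, src$y, target$x, target$y)
  else bilinear_weights(src$x, src$y, target$x, target$y)
  structure(list(W = W, src_dim = c(length(src$y), length(src$x)),
                 target_x = target$x, target_y = target$y, method = method),
            class = "regrid_weights")
}

apply_weights <- function(wts, z) {
  v <- wts$W %*% as.vector(z)  # column-major: [y, x] flattened by columns
  matrix(v, nrow = length(wts$target_y), ncol = length(wts$target_x))
}

#' Regrid a field or monthly stack onto a target grid
#'
#' @param obj a `raster_field` or `monthly_grid`.
#' @param target list with `x`, `y` (and optionally `elev`).
#' @param method interpolation method, see [regrid_weights()].
#' @param weights optional precomputed [regrid_weights()].
#' @return object of the same class on the target grid.
#' @export
regrid <- function(obj, target, method = c("patch_like", "bilinear"),
                   weights = NULL) {
  method <- match.arg(method)
  if (is.null(weights)) weights <- regrid_weights(obj, target, method)
  if (inherits(obj, "raster_field")) {
    return(raster_field(target$x, target$y, apply_weights(weights, obj$z)))
  }
  stopifnot(inherits(obj, "monthly_grid"))
  dd <- dim(obj$values)
  flat <- matrix(obj$values, nrow = dd[1] * dd[2])
  out <- weights$W %*% flat
  vals <- array(as.numeric(out),
                dim = c(length(target$y), length(target$x), dd[3], dd[4]))
  monthly_grid(target$x, target$y, vals, obj$years,
               elev = target$elev)
}

#' Fit per-cell, per-month bias model between two monthly grids
#'
#' Ordinary least squares of the fine-resolution series on the (regridded)
#' coarse series over the overlap years, one regression per cell and
#' calendar month. A zero-variance predictor falls back to an
#' intercept-only model (slope 0, intercept = mean of the fine series) with
#' a warning.
#'
#' @param coarse_on_fine `monthly_grid` of the coarse data on the fine grid.
#' @param fine `monthly_grid` of the fine data (same grid).
#' @param overlap_years years used for fitting (at least 10).
#' @return list of class `bias_model`: arrays `slope`, `intercept`
#'   `[y, x, 12]`.
#' @export
fit_bias <- function(coarse_on_fine, fine, overlap_years) {
  stopifnot(length(overlap_years) >= 10)
  ic <- match(overlap_years, coarse_on_fine$years)
  jf <- match(overlap_years, fine$years)
  if (anyNA(ic) || anyNA(jf)) stop("overlap years not covered by both grids")
  dd <- dim(fine$values)[1:2]
  slope <- intercept <- array(NA_real_, dim = c(dd, 12))
  degenerate <- 0L
  for (mo in 1:12) {
    xs <- matrix(coarse_on_fine$values[, , mo, ic], nrow = prod(dd))
    ys <- matrix(fine$values[, , mo, jf], nrow = prod(dd))
    mx <- rowMeans(xs); my <- rowMeans(ys)
    sxx <- rowSums((xs - mx)^2)
    sxy <- rowSums((xs - mx) * (ys - my))
    b <- ifelse(sxx > 0, sxy / sxx, 0)
    degenerate <- degenerate + sum(sxx == 0)
    slope[, , mo] <- b
    intercept[, , mo] <- my - b * mx
  }
  if (degenerate > 0)
    warning(degenerate, " cell-month regression(s) with zero predictor ",
            "variance: intercept-only fallback")
  structure(list(slope = slope, intercept = intercept,
                 overlap_years = overlap_years),
            class = "bias_model")
}

#' Apply a bias model and splice two monthly datasets
#'
#' Years strictly before `splice_year` come from the bias-corrected coarse
#' data (`slope * coarse + intercept`); years from `splice_year` on come
#' from the fine dataset directly.
#'
#' @param coarse `monthly_grid` (on the fine grid) covering the early years.
#' @param fine `monthly_grid` covering the later years.
#' @param bias a [fit_bias()] model.
#' @param splice_year first year taken from the fine data (default 1961).
#' @return fused `monthly_grid` covering both spans.
#' @export
apply_bias <- function(coarse, fine, bias, splice_year = 1961) {
  stopifnot(inherits(bias, "bias_model"))
  early <- coarse$years[coarse$years < splice_year]
  late <- fine$years[fine$years >= splice_year]
  years <- c(early, late)
  dd <- dim(fine$values)[1:2]
  vals <- array(NA_real_, dim = c(dd, 12, length(years)))
  for (i in seq_along(early)) {
    iy <- match(early[i], coarse$years)
    for (mo in 1:12)
      vals[, , mo, i] <- bias$slope[, , mo] * coarse$values[, , mo, iy] +
        bias$intercept[, , mo]
  }
  off <- length(early)
  for (i in seq_along(late)) {
    iy <- match(late[i], fine$years)
    vals[, , , off + i] <- fine$values[, , , iy]
  }
  monthly_grid(fine$x, fine$y, vals, years, elev = fine$elev)
}

index_months <- function(index_name) {
  switch(index_name,
         annual = 1:12,
         summer_half = 4:9,
         winter_half = c(10:12, 1:3),
         spring = 3:6,
         stop("unknown index: ", index_name))
}

#' 30-year mean temperature index field
#'
#' Per cell: mean over the index's months within each year, then mean over
#' the period's years. The winter half-year (October-March) crosses the
#' year boundary and is assigned to the calendar year of its January-March
#' part (i.e. index year `y` uses Oct-Dec of `y - 1`).
#'
#' @param grid a `monthly_grid`.
#' @param index_name one of `"annual"`, `"summer_half"`, `"winter_half"`,
#'   `"spring"`.
#' @param period_years the years averaged over (e.g. `1906:1935`).
#' @return list of class `index_field`: `x`, `y`, `z`, `index`, `period`,
#'   `elev`.
#' @export
temperature_index <- function(grid, index_name, period_years) {
  months <- index_months(index_name)
  need <- if (index_name == "winter_half")
    sort(unique(c(period_years, period_years - 1))) else period_years
  if (!all(need %in% grid$years))
    stop("period not fully covered: need years ",
         paste(range(need), collapse = "-"))
  dd <- dim(grid$values)[1:2]
  acc <- matrix(0, dd[1], dd[2])
  for (yr in period_years) {
    ann <- matrix(0, dd[1], dd[2])
    for (mo in months) {
      use_year <- if (index_name == "winter_half" && mo >= 10) yr - 1 else yr
      iy <- match(use_year, grid$years)
      ann <- ann + grid$values[, , mo, iy]
    }
    acc <- acc + ann / length(months)
  }
  structure(list(x = grid$x, y = grid$y, z = acc / length(period_years),
                 index = index_name,
                 period = paste(range(period_years), collapse = "-"),
                 elev = grid$elev),
            class = c("index_field", "raster_field"))
}

#' Lapse-rate downscaling of an index field to a DEM
#'
#' Subtracts the vertical temperature dependence (`gamma * elevation`) on
#' the source grid, interpolates the residuals to the DEM grid with the
#' patch-like scheme, and adds back `gamma * DEM elevation`.
#'
#' @param field an `index_field` whose grid carries an `elev` matrix.
#' @param dem a `raster_field` of elevations (meters) on the target grid.
#' @param lapse vertical gradient in K per km (default -6.68; must be
#'   negative).
#' @param method interpolation for the residuals (default `"patch_like"`).
#' @param weights optional precomputed [regrid_weights()].
#' @return downscaled `index_field` on the DEM grid.
#' @export
downscale <- function(field, dem, lapse = -6.68,
                      method = c("patch_like", "bilinear"), weights = NULL) {
  method <- match.arg(method)
  if (is.null(field$elev)) stop("source grid has no elevation field")
  stopifnot(lapse < 0)
  resid <- field$z - lapse * field$elev / 1000
  rf <- raster_field(field$x, field$y, resid)
  rr <- regrid(rf, dem, method = method, weights = weights)
  structure(list(x = dem$x, y = dem$y,
                 z = rr$z + lapse * dem$z / 1000,
                 index = field$index, period = field$period, elev = dem$z),
            class = c("index_field", "raster_field"))
}

#' Equivalent-elevation shift of a temperature change
#'
#' Expresses a warming `delta_T` as the upslope displacement of isotherms
#' implied by the vertical temperature gradient: `shift = delta_T / |gamma|`
#' in meters. With the default gradient of -6.68 K/km, 1 K corresponds to
#' about 150 m.
#'
#' @param delta_T temperature change in K.
#' @param lapse vertical gradient in K per km (nonzero).
#' @return shift in meters.
#' @export
equivalent_shift <- function(delta_T, lapse = -6.68) {
  if (lapse == 0) stop("zero vertical gradient")
  delta_T / abs(lapse) * 1000
}

#' Mean index value per elevation zone
#'
#' @param field an `index_field` (or `raster_field`).
#' @param dem elevation `raster_field` on the same grid.
#' @param zones list of `c(low, high)` elevation intervals in masl
#'   (closed).
#' @return named numeric vector of zone means.
#' @export
zone_means <- function(field, dem, zones) {
  stopifnot(all(dim(field$z) == dim(dem$z)))
  out <- vapply(zones, function(zn) {
    sel <- dem$z >= zn[1] & dem$z <= zn[2]
    if (!any(sel)) stop("empty elevation zone ", zn[1], "-", zn[2])
    mean(field$z[sel])
  }, 0)
  names(out) <- vapply(zones, function(zn)
    paste0(zn[1], "-", zn[2]), "")
  out
}

#' Run the full climate pipeline on a synthetic scenario
#'
#' Generates the two-resolution synthetic climate world, regrids the coarse
#' stack onto the fine grid (patch-like), fits and applies the bias
#' correction with the configured splice year, computes the spring index
#' for both 30-year periods, downscales each to the DEM, and returns the
#' recovered between-period spring warming (domain mean difference in K).
#'
#' @param config a [scenario_config()].
#' @param splice_year first year taken from the fine data (default 1961).
#' @param periods named list of the two 30-year spans.
#' @return recovered warming in K; the downscaled fields are attached as
#'   attribute `"fields"`.
#' @export
run_climate_recovery <- function(config, splice_year = 1961,
                                 periods = list(historic = 1906:1935,
                                                recent = 1991:2020)) {
  cl <- gen_climate(config)
  wts <- regrid_weights(cl$coarse, cl$fine, "patch_like")
  cof <- regrid(cl$coarse, cl$fine, weights = wts)
  overlap <- intersect(cl$coarse$years, cl$fine$years)
  overlap <- overlap[overlap >= splice_year][1:30]
  bias <- fit_bias(cof, cl$fine, overlap)
  fused <- apply_bias(cof, cl$fine, bias, splice_year = splice_year)
  dem_wts <- regrid_weights(cl$fine, cl$dem, "patch_like")
  fields <- lapply(periods, function(yrs) {
    fld <- temperature_index(fused, "spring", yrs)
    fld$elev <- cl$fine$elev
    downscale(fld, cl$dem, lapse = config$lapse, weights = dem_wts)
  })
  out <- mean(fields$recent$z) - mean(fields$historic$z)
  attr(out, "fields") <- fields
  out
}

#' Glacier area reduction
#'
#' @param area_old_km2,area_new_km2 glaciated areas in square kilometers.
#' @return percent reduction `100 (old - new) / old` (negative if the area
#'   grew).
#' @export
glacier_change <- function(area_old_km2, area_new_km2) {
  stopifnot(area_old_km2 > 0, area_new_km2 > 0)
  100 * (area_old_km2 - area_new_km2) / area_old_km2
}
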
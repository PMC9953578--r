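#' Sørensen dissimilarity matrix
#'
#' Pairwise Sørensen dissimilarity on a binary incidence matrix:
#' `d = (b + c) / (2a + b + c)` with `a` the number of shared species and
#' `b`, `c` the species unique to each unit. This equals Bray–Curtis
#' dissimilarity computed on presence/absence data. A pair of units with no
#' species at all is defined as distance 0 with a warning.
#'
#' @param incidence binary units-by-species matrix.
#' @return a `dist` object with unit labels.
#' @export
sorensen_matrix <- function(incidence) {
  m <- as.matrix(incidence)
  if (!all(m %in% c(0, 1))) stop("incidence matrix must be binary (0/1)")
  if (nrow(m) < 2) stop("need at least 2 sampling units")
  s <- rowSums(m)                 # species totals per unit
  a <- m %*% t(m)                 # shared species counts
  denom <- outer(s, s, `+`)       # 2a + b + c
  d <- (denom - 2 * a) / denom
  if (any(denom == 0 & upper.tri(denom))) {
    warning("unit pair(s) with no species: dissimilarity defined as 0")
    d[denom == 0] <- 0
  }
  diag(d) <- 0
  stats::as.dist(d)
}

#' Ward hierarchical clustering of sampling units
#'
#' Agglomerative clustering with Ward's minimum variance criterion via the
#' Lance–Williams update. `ward_d` applies the update directly to the
#' supplied dissimilarities; `ward_d2` applies it to squared dissimilarities
#' and reports square-rooted merge heights (the criterion Ward originally
#' proposed for squared Euclidean distances).
#'
#' @param dissim a `dist` object.
#' @param variant `"ward_d"` (default) or `"ward_d2"`.
#' @return an object of class `hclust`.
#' @export
ward_cluster <- function(dissim, variant = c("ward_d", "ward_d2")) {
  variant <- match.arg(variant)
  dissim <- stats::as.dist(dissim)
  if (attr(dissim, "Size") < 2) stop("need at least 2 units to cluster")
  method <- if (variant == "ward_d") "ward.D" else "ward.D2"
  stats::hclust(dissim, method = method)
}

#' Cut a dendrogram at a fixed height
#'
#' Removes all merges strictly above `height` and labels the resulting
#' clusters `A`, `B`, ... in dendrogram leaf order (the leftmost leaf's
#' cluster is `A`).
#'
#' @param dendrogram an `hclust` object.
#' @param height cut height (same scale as the merge heights).
#' @return named character vector of cluster labels, one per leaf, in the
#'   original input order.
#' @export
cut_tree <- function(dendrogram, height) {
  stopifnot(inherits(dendrogram, "hclust"), height >= 0)
  raw <- stats::cutree(dendrogram, h = height)
  # relabel by first appearance along the leaf order
  first <- raw[dendrogram$order]
  lev <- unique(first)
  labels <- stats::setNames(LETTERS[seq_along(lev)], lev)
  out <- labels[as.character(raw)]
  names(out) <- names(raw)
  out
}

#' Cross elevation clusters with sampling period
#'
#' Combines the elevation-cluster labels with the sampling period of each
#' unit into crossed analysis groups such as `"1935/1936 A"` and attaches a
#' per-cluster summary (size, median elevation).
#'
#' @param labels named character vector from [cut_tree()].
#' @param units sampling-unit data.frame (needs `id`, `year`, `mean_elev`).
#' @param periods named list mapping period label to years.
#' @param period_names optional named character vector mapping period label
#'   to the display name used in the crossed group (default
#'   `historic = "1935/1936"`, `recent = "2020"`).
#' @return data.frame with one row per unit: `id`, `cluster`, `period`,
#'   `group`; summary table in attribute `"summary"`.
#' @export
cross_with_period <- function(labels, units,
                              periods = list(historic = c(1935L, 1936L),
                                             recent = 2020L),
                              period_names = c(historic = "1935/1936",
                                               recent = "2020")) {
  stopifnot(all(units$id %in% names(labels)))
  per <- period_of(units$year, periods)
  if (anyNA(per))
    stop("unit year(s) outside declared periods: ",
         paste(unique(units$year[is.na(per)]), collapse = ", "))
  cl <- unname(labels[units$id])
  grp <- paste(period_names[per], cl)
  out <- data.frame(id = units$id, cluster = cl,
                    period = unname(period_names[per]), group = grp,
                    stringsAsFactors = FALSE)
  smry <- do.call(rbind, lapply(split(units$mean_elev, cl), function(e) {
    data.frame(n = length(e), median_elev = stats::median(e))
  }))
  smry$cluster <- rownames(smry)
  attr(out, "summary") <- smry[, c("cluster", "n", "median_elev")]
  out
}

#' Export a dendrogram as a Newick string
#'
#' Branch lengths are derived from merge heights (each branch spans the
#' height difference between a node and its parent merge).
#'
#' @param dendrogram an `hclust` object.
#' @param path optional file to write to.
#' @return the Newick string, invisibly if written to file.
#' @export
dendrogram_newick <- function(dendrogram, path = NULL) {
  stopifnot(inherits(dendrogram, "hclust"))
  n <- length(dendrogram$labels)
  node_str <- function(i, parent_h) {
    if (i < 0) {  # leaf (hclust convention: negative = singleton)
      sprintf("%s:%.10g", dendrogram$labels[-i], parent_h)
    } else {
      h <- dendrogram$height[i]
      sprintf("(%s,%s):%.10g",
              node_str(dendrogram$merge[i, 1], h),
              node_str(dendrogram$merge[i, 2], h),
              parent_h - h)
    }
  }
  top <- nrow(dendrogram$merge)
  h <- dendrogram$height[top]
  nwk <- sprintf("(%s,%s);",
                 node_str(dendrogram$merge[top, 1], h),
                 node_str(dendrogram$merge[top, 2], h))
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
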
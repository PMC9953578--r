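#' PERMANOVA: permutational multivariate analysis of variance
#'
#' Partitions the total sum of squared dissimilarities
#' (`SS_total = sum_{i<j} d_ij^2 / n`) among terms in the supplied order
#' (sequential, Type I sums of squares) via projections of the
#' Gower-centered matrix, with a pseudo-F per term and p-values from free
#' permutation of the units.
#'
#' @param dissim a `dist` object.
#' @param terms data.frame of explanatory variables (columns are terms, in
#'   test order), one row per unit.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed (mandatory unless `exact = TRUE`).
#' @param exact enumerate all `n!` permutations instead of sampling
#'   (only for `n <= 7`); the p-value is then exact and no seed is used.
#' @return data.frame of class `permanova_table`: per term `df`, `ss`, `f`,
#'   `r2`, `p`, plus Residual and Total rows; attributes `n_perm`, `seed`,
#'   `n`.
#' @export
permanova <- function(dissim, terms, n_perm = 999, seed, exact = FALSE) {
  if (missing(seed)) {
    if (!exact) stop("a permutation seed is required")
    seed <- 0L
  }
  stopifnot(n_perm >= 1)
  D <- as.matrix(stats::as.dist(dissim))
  n <- nrow(D)
  terms <- as.data.frame(terms)
  stopifnot(nrow(terms) == n)
  for (nm in names(terms)) {
    v <- terms[[nm]]
    if (length(unique(v)) < 2) stop("term with a single level: ", nm)
  }
  J <- diag(n) - 1 / n
  G <- -0.5 * J %*% (D^2) %*% J
  ss_total <- sum(diag(G))

  Ms <- lapply(seq_along(terms), function(j)
    constraint_matrix(terms[, seq_len(j), drop = FALSE]))
  Q_list <- lapply(Ms, function(M) qr.Q(qr(M)))
  cum_df <- vapply(Ms, ncol, integer(1))
  dfs <- diff(c(0, cum_df))
  df_resid <- n - 1 - sum(dfs)

  # trace of H_j G for cumulative hat matrices, via orthonormal bases
  tr_ss <- function(Gp) {
    cum <- vapply(Q_list, function(Q) sum(crossprod(Q, Gp) * t(Q)), 0)
    diff(c(0, cum))
  }
  ss_terms <- tr_ss(G)
  ss_resid <- ss_total - sum(ss_terms)
  f_obs <- (ss_terms / dfs) / (ss_resid / df_resid)

  perm_f <- function(idx) {
    ssp <- tr_ss(G[idx, idx])
    (ssp / dfs) / ((ss_total - sum(ssp)) / df_resid)
  }
  if (exact) {
    if (n > 7) stop("exact enumeration limited to n <= 7")
    perms <- all_permutations(n)
    fs <- vapply(perms, perm_f, f_obs)
    fs <- matrix(fs, nrow = length(f_obs))
    p <- rowMeans(fs >= f_obs - 1e-12)
    n_perm <- length(perms)
  } else {
    set.seed(as.integer(seed))
    count <- rep(1L, length(f_obs))
    for (b in seq_len(n_perm)) {
      fp <- perm_f(sample.int(n))
      count <- count + (fp >= f_obs - 1e-12)
    }
    p <- count / (n_perm + 1)
  }
  out <- data.frame(term = c(names(terms), "Residual", "Total"),
                    df = c(dfs, df_resid, n - 1),
                    ss = c(ss_terms, ss_resid, ss_total),
                    f = c(f_obs, NA, NA),
                    r2 = c(ss_terms / ss_total, ss_resid / ss_total, 1),
                    p = c(p, NA, NA))
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n") <- n
  class(out) <- c("permanova_table", "data.frame")
  out
}

all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in 0:(n - 1L)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos)
  }
  out
}

# geometric (spatial) median by Weiszfeld iteration
spatial_median <- function(X, tol = 1e-8, maxit = 500) {
  m <- colMeans(X)
  for (it in seq_len(maxit)) {
    d <- sqrt(rowSums(sweep(X, 2, m)^2))
    if (any(d < 1e-12)) return(m)
    w <- 1 / d
    m_new <- colSums(X * w) / sum(w)
    if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
    m <- m_new
  }
  m
}

#' Multivariate homogeneity of group dispersions
#'
#' Computes each unit's distance to its group center in the full principal
#' coordinate space (real and imaginary axes; imaginary squared distances
#' are subtracted, negative results truncated at zero) and tests equality of
#' mean dispersion among groups by one-way ANOVA. Mirrors the
#' betadisper/PERMDISP approach.
#'
#' @param dissim a `dist` object.
#' @param groups factor or character vector of group labels, one per unit.
#' @param center `"spatial_median"` (default) or `"centroid"`.
#' @return list of class `dispersion_result`: `distances` (per unit),
#'   `group_means`, and the ANOVA `f`, `df`, `p`, `anova` table.
#' @export
beta_dispersion <- function(dissim, groups,
                            center = c("spatial_median", "centroid")) {
  center <- match.arg(center)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  pc <- pcoa(dissim)
  R <- pc$points
  I <- pc$imaginary_points
  n <- nrow(R)
  stopifnot(length(groups) == n)
  d2 <- numeric(n)
  for (g in levels(groups)) {
    idx <- which(groups == g)
    Rg <- R[idx, , drop = FALSE]
    Ig <- I[idx, , drop = FALSE]
    if (center == "centroid") {
      cr <- colMeans(Rg)
      ci <- if (ncol(Ig)) colMeans(Ig) else numeric(0)
    } else {
      cr <- if (length(idx) > 1) spatial_median(Rg) else Rg[1, ]
      ci <- if (ncol(Ig)) {
        if (length(idx) > 1) spatial_median(Ig) else Ig[1, ]
      } else numeric(0)
    }
    dr <- rowSums(sweep(Rg, 2, cr)^2)
    di <- if (ncol(Ig)) rowSums(sweep(Ig, 2, ci)^2) else 0
    d2[idx] <- pmax(dr - di, 0)
  }
  dist_to_center <- sqrt(d2)
  fit <- stats::aov(dist_to_center ~ groups)
  tab <- summary(fit)[[1]]
  structure(list(distances = stats::setNames(dist_to_center, rownames(R)),
                 groups = groups,
                 group_means = tapply(dist_to_center, groups, mean),
                 f = tab$`F value`[1],
                 df = c(tab$Df[1], tab$Df[2]),
                 p = tab$`Pr(>F)`[1],
                 anova = tab, center = center),
            class = "dispersion_result")
}

#' Kruskal-Wallis rank sum test (tie-corrected)
#'
#' Closed-form H statistic with the standard tie correction and a
#' chi-squared reference distribution on `groups - 1` degrees of freedom.
#' All observations tied gives `H = 0`, `p = 1`.
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return list of class `rank_test_result`: `h`, `df`, `p`, `group_sizes`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  stopifnot(length(values) == length(groups))
  groups <- droplevels(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  if (any(tabulate(groups) < 1)) stop("empty group")
  N <- length(values)
  r <- rank(values)
  Rg <- tapply(r, groups, sum)
  ng <- tabulate(groups)
  H <- 12 / (N * (N + 1)) * sum(Rg^2 / ng) - 3 * (N + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (corr == 0) {
    H <- 0; p <- 1
  } else {
    H <- H / corr
    p <- stats::pchisq(H, df = nlevels(groups) - 1, lower.tail = FALSE)
  }
  structure(list(h = H, df = nlevels(groups) - 1, p = p,
                 group_sizes = stats::setNames(ng, levels(groups))),
            class = "rank_test_result")
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi-squared = %.4g, df = %d, p = %.4g\n",
              x$h, x$df, x$p))
  invisible(x)
}

#' Multiplicity adjustment of p-values
#'
#' Implements the Holm step-down, Bonferroni and Benjamini-Hochberg
#' adjustments from their definitions.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param method `"holm"` (default), `"bonferroni"` or
#'   `"benjamini_hochberg"`.
#' @return adjusted p-values, same order as input.
#' @export
adjust_pvalues <- function(pvalues,
                           method = c("holm", "bonferroni",
                                      "benjamini_hochberg")) {
  method <- match.arg(method)
  m <- length(pvalues)
  if (m == 0) stop("empty p-value vector")
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  if (m == 1) return(pvalues)
  switch(method,
    bonferroni = pmin(1, m * pvalues),
    holm = {
      o <- order(pvalues)
      adj <- pmin(1, (m - seq_len(m) + 1) * pvalues[o])
      adj <- cummax(adj)
      out <- numeric(m); out[o] <- adj
      out
    },
    benjamini_hochberg = {
      o <- order(pvalues, decreasing = TRUE)
      adj <- pmin(1, m / (m - seq_len(m) + 1) * pvalues[o])
      adj <- cummin(adj)
      out <- numeric(m); out[o] <- adj
      out
    })
}
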
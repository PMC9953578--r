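#' Principal coordinates analysis
#'
#' Classical metric scaling of a dissimilarity matrix: the Gower-centered
#' matrix `G = -1/2 J D^2 J` is eigendecomposed and coordinates on the real
#' axes are `eigenvector * sqrt(eigenvalue)` for positive eigenvalues.
#' Negative eigenvalues (non-Euclidean input) are reported as negative
#' inertia; the optional Lingoes correction adds a constant to the squared
#' off-diagonal dissimilarities to remove them.
#'
#' @param dissim a `dist` object.
#' @param correction `"none"` (default) or `"lingoes"`.
#' @return list of class `pcoa_result`: `eigenvalues` (descending, may be
#'   negative), `points` (units x real axes), `imaginary_points` (axes for
#'   negative eigenvalues, scaled by `sqrt(-eigenvalue)`), `total_inertia`
#'   (sum of positive eigenvalues), `negative_inertia`, `correction`.
#' @export
pcoa <- function(dissim, correction = c("none", "lingoes")) {
  correction <- match.arg(correction)
  D <- as.matrix(stats::as.dist(dissim))
  n <- nrow(D)
  if (n < 2) stop("need at least 2 units")
  gower <- function(D2) {
    J <- diag(n) - 1 / n
    -0.5 * J %*% D2 %*% J
  }
  G <- gower(D^2)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- 1e-9 * max(abs(e$values), 1)
  if (correction == "lingoes" && min(e$values) < -tol) {
    cc <- -min(e$values)
    D2 <- D^2 + 2 * cc
    diag(D2) <- 0
    G <- gower(D2)
    e <- eigen((G + t(G)) / 2, symmetric = TRUE)
    tol <- 1e-9 * max(abs(e$values), 1)
  }
  pos <- which(e$values > tol)
  neg <- which(e$values < -tol)
  pts <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), length(pos))
  dimnames(pts) <- list(rownames(D), paste0("PCo", seq_along(pos)))
  ipts <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), length(neg))
  rownames(ipts) <- rownames(D)
  structure(list(eigenvalues = e$values, points = pts,
                 imaginary_points = ipts,
                 total_inertia = sum(e$values[pos]),
                 negative_inertia = -sum(e$values[neg]),
                 correction = correction),
            class = "pcoa_result")
}

# centered model matrix without intercept; drops collinear columns
constraint_matrix <- function(data) {
  stopifnot(is.data.frame(data))
  M <- stats::model.matrix(~ ., data = data)[, -1, drop = FALSE]
  M <- scale(M, center = TRUE, scale = FALSE)
  q <- qr(M)
  if (q$rank < ncol(M)) {
    drop <- colnames(M)[-q$pivot[seq_len(q$rank)]]
    warning("dropping collinear constraint column(s): ",
            paste(drop, collapse = ", "))
    M <- M[, q$pivot[seq_len(q$rank)], drop = FALSE]
  }
  M
}

#' Canonical analysis of principal coordinates (distance-based RDA)
#'
#' Regresses the principal-coordinate matrix of a dissimilarity matrix on a
#' table of constraining variables; constrained axes come from the singular
#' value decomposition of the fitted values, residual axes from the
#' residuals. Numeric constraints are centered, categorical constraints
#' dummy-coded. Imaginary (negative-eigenvalue) axes are excluded from the
#' analysis but their inertia is reported.
#'
#' @param dissim a `dist` object.
#' @param constraints data.frame of constraining variables, one row per
#'   unit, in the order of the dissimilarity labels.
#' @param incidence optional binary incidence matrix (same row order); when
#'   supplied, species scores are computed as presence-weighted averages of
#'   unit scores.
#' @return list of class `cap_model`: eigenvalues and scores of constrained
#'   (`CAP1`, ...) and residual (`MDS1`, ...) axes, inertia decomposition,
#'   `unit_scores` (weighted-average scores), `lc_scores` (fitted-value
#'   scores), `species_scores`, `biplot` arrows for the constraints, and the
#'   ingredients needed for permutation tests.
#' @export
cap <- function(dissim, constraints = NULL, incidence = NULL) {
  pc <- pcoa(dissim)
  X <- pc$points
  n <- nrow(X)
  if (is.null(constraints) || ncol(as.data.frame(constraints)) == 0) {
    M <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    constraints <- as.data.frame(constraints)
    if (nrow(constraints) != n)
      stop("constraints must have one row per unit (", n, ")")
    M <- constraint_matrix(constraints)
  }
  m <- ncol(M)
  if (m >= n - 1 && m > 0) stop("too many constraints (m >= n - 1)")
  tol <- 1e-9 * max(pc$eigenvalues, 1)
  if (m > 0) {
    qrM <- qr(M)
    fitted <- qr.fitted(qrM, X)
    resid <- X - fitted
    sv <- svd(fitted)
    keep <- which(sv$d^2 > tol)
    cap_eig <- sv$d[keep]^2
    axes <- sv$v[, keep, drop = FALSE]
    lc <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
    wa <- X %*% axes
    dimnames(wa) <- dimnames(lc) <-
      list(rownames(X),
           if (length(keep)) paste0("CAP", seq_along(keep)) else NULL)
    # biplot arrows: correlation of constraint columns with lc axes
    bip <- if (length(keep)) {
      b <- stats::cor(M, lc)
      rownames(b) <- colnames(M)
      b
    } else NULL
  } else {
    qrM <- NULL
    fitted <- matrix(0, n, ncol(X))
    resid <- X
    cap_eig <- numeric(0)
    wa <- lc <- matrix(numeric(0), nrow = n, ncol = 0)
    bip <- NULL
  }
  sv_r <- svd(resid)
  rkeep <- which(sv_r$d^2 > tol)
  res_eig <- sv_r$d[rkeep]^2
  res_scores <- sv_r$u[, rkeep, drop = FALSE] %*%
    diag(sv_r$d[rkeep], length(rkeep))
  colnames(res_scores) <- paste0("MDS", seq_along(rkeep))
  rownames(res_scores) <- rownames(X)
  unit_scores <- cbind(wa, res_scores)
  species_scores <- NULL
  if (!is.null(incidence)) {
    w <- as.matrix(incidence)
    stopifnot(nrow(w) == n)
    cs <- colSums(w)
    species_scores <- crossprod(w, unit_scores) / cs
    species_scores <- species_scores[cs > 0, , drop = FALSE]
  }
  structure(list(
    eigenvalues = cap_eig, residual_eigenvalues = res_eig,
    constrained_inertia = sum(cap_eig),
    total_inertia = pc$total_inertia,
    negative_inertia = pc$negative_inertia,
    unit_scores = unit_scores, lc_scores = lc,
    species_scores = species_scores, biplot = bip,
    pcoa = pc, X = X, qr = qrM, n = n, m = m,
    constraint_names = if (m > 0) colnames(M) else character(0)),
    class = "cap_model")
}

#' @export
print.cap_model <- function(x, ...) {
  cat("<cap_model> n =", x$n, " constraints =", x$m, "\n")
  cat("  total inertia:", format(x$total_inertia, digits = 5),
      " constrained:", format(x$constrained_inertia, digits = 5),
      sprintf("(%.2f%%)", 100 * x$constrained_inertia / x$total_inertia), "\n")
  if (length(x$eigenvalues))
    cat("  constrained eigenvalues:",
        paste(format(x$eigenvalues, digits = 4), collapse = ", "), "\n")
  invisible(x)
}

# model/term sums of squares under a row permutation of the PCoA matrix.
# Q_list holds cumulative orthonormal bases (qr.Q) for term 1, terms 1:2, ...
seq_ss <- function(X, Q_list) {
  ss <- numeric(length(Q_list))
  prev <- 0
  for (j in seq_along(Q_list)) {
    cur <- sum(crossprod(Q_list[[j]], X)^2)
    ss[j] <- cur - prev
    prev <- cur
  }
  ss
}

#' Permutation ANOVA for a CAP model
#'
#' Tests the constrained variation against an unconstrained null model by
#' freely permuting the rows of the principal-coordinate matrix.
#' `by = "model"` gives one overall test; `by = "terms"` gives sequential
#' tests in the order the constraints were supplied, all against the full
#' model's residual.
#'
#' @param model a `cap_model` with at least one constraint, fitted with
#'   `cap(dissim, constraints)` where `constraints` kept term identity
#'   (pass `terms` as a list of column subsets to override).
#' @param constraints the constraint data.frame used to fit the model
#'   (needed for `by = "terms"`; each column is a term).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed (mandatory; logged in the result).
#' @param by `"model"` or `"terms"`.
#' @return data.frame of class `permutation_anova`: one row per term (plus a
#'   residual row) with `df`, `ss`, `f`, `p`; attributes `n_perm`, `seed`,
#'   `n`.
#' @export
permutation_anova <- function(model, constraints = NULL, n_perm = 999,
                              seed, by = c("model", "terms")) {
  by <- match.arg(by)
  stopifnot(inherits(model, "cap_model"), n_perm >= 1)
  if (model$m == 0) stop("model has no constraints to test")
  if (missing(seed)) stop("a permutation seed is required")
  X <- model$X
  n <- model$n
  ss_total <- sum(X^2)

  if (by == "model") {
    Q_list <- list(qr.Q(model$qr))
    dfs <- model$m
    term_names <- "Model"
  } else {
    if (is.null(constraints)) stop("`constraints` needed for by = \"terms\"")
    constraints <- as.data.frame(constraints)
    Ms <- lapply(seq_along(constraints), function(j)
      constraint_matrix(constraints[, seq_len(j), drop = FALSE]))
    Q_list <- lapply(Ms, function(M) qr.Q(qr(M)))
    cum_df <- vapply(Ms, ncol, integer(1))
    dfs <- diff(c(0, cum_df))
    term_names <- names(constraints)
  }
  df_resid <- n - 1 - sum(dfs)
  ss_terms <- seq_ss(X, Q_list)
  ss_resid <- ss_total - sum(ss_terms)
  f_obs <- (ss_terms / dfs) / (ss_resid / df_resid)

  set.seed(as.integer(seed))
  count <- rep(1L, length(f_obs))  # includes observed
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n)
    Xp <- X[idx, , drop = FALSE]
    ssp <- seq_ss(Xp, Q_list)
    ssrp <- ss_total - sum(ssp)
    fp <- (ssp / dfs) / (ssrp / df_resid)
    count <- count + (fp >= f_obs - 1e-12)
  }
  p <- count / (n_perm + 1)
  out <- data.frame(term = c(term_names, "Residual"),
                    df = c(dfs, df_resid),
                    ss = c(ss_terms, ss_resid),
                    f = c(f_obs, NA),
                    p = c(p, NA))
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- as.integer(seed)
  attr(out, "n") <- n
  class(out) <- c("permutation_anova", "data.frame")
  out
}

#' Stepwise constraint selection for CAP
#'
#' Bidirectional (add/drop) selection among candidate constraining
#' variables. At each step the candidate with the smallest permutation
#' p-value below `alpha_in` (ties broken by larger F) is added; included
#' terms whose marginal p-value exceeds `alpha_out` are dropped. Stops when
#' no move is possible. Significance of a candidate is assessed by the
#' sequential test of that term entered last into the current model.
#'
#' @param dissim a `dist` object.
#' @param candidates data.frame of candidate variables (columns are terms).
#' @param alpha_in,alpha_out inclusion / exclusion thresholds
#'   (defaults 0.05 / 0.10).
#' @param n_perm permutations per test (default 199).
#' @param seed integer seed.
#' @param incidence optional incidence matrix forwarded to [cap()].
#' @return the selected `cap_model` (possibly the null model) with the
#'   selected term names in `$selected` and a selection `$trace` data.frame.
#' @export
stepwise_select <- function(dissim, candidates, alpha_in = 0.05,
                            alpha_out = 0.10, n_perm = 199, seed,
                            incidence = NULL) {
  if (missing(seed)) stop("a permutation seed is required")
  candidates <- as.data.frame(candidates)
  included <- character(0)
  trace <- list()
  seed_i <- as.integer(seed)

  test_last <- function(terms_order) {
    # p and F of the last term in `terms_order`, sequential fit
    mdl <- cap(dissim, candidates[, terms_order, drop = FALSE])
    a <- permutation_anova(mdl, candidates[, terms_order, drop = FALSE],
                           n_perm = n_perm, seed = seed_i, by = "terms")
    k <- length(terms_order)
    c(p = a$p[k], f = a$f[k])
  }

  repeat {
    moved <- FALSE
    # forward
    pool <- setdiff(names(candidates), included)
    if (length(pool)) {
      stats_in <- t(vapply(pool, function(v) test_last(c(included, v)),
                           c(p = 0, f = 0)))
      ok <- which(stats_in[, "p"] < alpha_in)
      if (length(ok)) {
        best <- ok[order(stats_in[ok, "p"], -stats_in[ok, "f"])][1]
        v <- pool[best]
        included <- c(included, v)
        trace[[length(trace) + 1]] <- data.frame(
          action = "add", term = v, p = stats_in[best, "p"],
          f = stats_in[best, "f"])
        moved <- TRUE
      }
    }
    # backward
    if (length(included) > 1) {
      stats_out <- t(vapply(included, function(v)
        test_last(c(setdiff(included, v), v)), c(p = 0, f = 0)))
      worst <- which.max(stats_out[, "p"])
      if (stats_out[worst, "p"] > alpha_out) {
        v <- included[worst]
        included <- setdiff(included, v)
        trace[[length(trace) + 1]] <- data.frame(
          action = "drop", term = v, p = stats_out[worst, "p"],
          f = stats_out[worst, "f"])
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  model <- cap(dissim,
               if (length(included)) candidates[, included, drop = FALSE]
               else NULL,
               incidence = incidence)
  model$selected <- included
  model$trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(action = character(), term = character(),
               p = numeric(), f = numeric())
  model
}

#' Adjusted R-squared of a CAP model
#'
#' `R^2` is the constrained share of total (real-axis) inertia; the
#' adjustment is Ezekiel's correction
#' `1 - (1 - R^2) (n - 1) / (n - m - 1)` with `m` constraint columns.
#'
#' @param model a `cap_model`.
#' @return list with `r_squared` and `adj_r_squared`.
#' @export
adjusted_r2 <- function(model) {
  stopifnot(inherits(model, "cap_model"))
  n <- model$n; m <- model$m
  if (n - m - 1 <= 0) stop("adjusted R^2 undefined: n - m - 1 <= 0")
  r2 <- model$constrained_inertia / model$total_inertia
  list(r_squared = r2,
       adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - m - 1))
}

#' Fit environmental vectors into an ordination plane
#'
#' For each variable, finds the direction in the (first two) ordination axes
#' that maximizes its correlation with the unit scores (least-squares
#' projection), with a permutation test on the squared correlation.
#'
#' @param scores matrix of unit scores (first two columns used) or a
#'   `cap_model` (its `unit_scores` are used).
#' @param variables data.frame of numeric variables, one row per unit.
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @return data.frame: variable, direction cosines (`dx`, `dy`), `r2`, `p`.
#' @export
fit_vectors <- function(scores, variables, n_perm = 999, seed) {
  if (missing(seed)) stop("a permutation seed is required")
  if (inherits(scores, "cap_model")) scores <- scores$unit_scores
  S <- scale(as.matrix(scores)[, 1:2, drop = FALSE], center = TRUE,
             scale = FALSE)
  variables <- as.data.frame(variables)
  qrS <- qr(S)
  set.seed(as.integer(seed))
  n <- nrow(S)
  out <- lapply(names(variables), function(nm) {
    v <- as.numeric(variables[[nm]])
    v <- v - mean(v)
    sst <- sum(v^2)
    if (sst == 0) stop("zero-variance variable: ", nm)
    b <- qr.coef(qrS, v)
    b[is.na(b)] <- 0
    r2 <- sum(qr.fitted(qrS, v)^2) / sst
    dir <- b / sqrt(sum(b^2))
    cnt <- 1L
    for (i in seq_len(n_perm)) {
      vp <- v[sample.int(n)]
      r2p <- sum(qr.fitted(qrS, vp)^2) / sum(vp^2)
      if (r2p >= r2 - 1e-12) cnt <- cnt + 1L
    }
    data.frame(variable = nm, dx = dir[1], dy = dir[2], r2 = r2,
               p = cnt / (n_perm + 1))
  })
  out <- do.call(rbind, out)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- as.integer(seed)
  rownames(out) <- NULL
  out
}
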
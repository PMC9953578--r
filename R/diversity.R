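#' Incidence frequency summary for one assemblage
#'
#' @param incidence binary units-by-species matrix of one cluster group.
#' @return list of class `incidence_freqs`: `T` (number of sampling units),
#'   `Y` (incidence frequency per species), `S_obs`, `Q1` (uniques), `Q2`
#'   (duplicates), `U` (total incidences).
#' @export
incidence_freqs <- function(incidence) {
  m <- as.matrix(incidence)
  if (!length(m) || !nrow(m)) stop("empty incidence matrix")
  if (!all(m %in% c(0, 1))) stop("incidence matrix must be binary")
  Y <- colSums(m)
  Y <- Y[Y > 0]
  structure(list(T = nrow(m), Y = Y, S_obs = length(Y),
                 Q1 = sum(Y == 1), Q2 = sum(Y == 2), U = sum(Y)),
            class = "incidence_freqs")
}

as_freqs <- function(x) {
  if (inherits(x, "incidence_freqs")) x else incidence_freqs(x)
}

# Chao2-type estimate of the number of undetected species
chao2_undetected <- function(f) {
  with(f, if (Q2 == 0) (T - 1) / T * Q1 * (Q1 - 1) / 2
       else (T - 1) / T * Q1^2 / (2 * Q2))
}

#' Asymptotic richness (Chao2) of an incidence assemblage
#' @param freqs an `incidence_freqs` object or binary matrix.
#' @return estimated total species richness `S_obs + Q0_hat`.
#' @export
chao2_richness <- function(freqs) {
  f <- as_freqs(freqs)
  f$S_obs + chao2_undetected(f)
}

# expected frequency counts E[Q_k(t)] for a hypergeometric subsample of
# t <= T units; returns vector over k = 1..t
expected_Qk <- function(f, t) {
  stopifnot(t <= f$T, t >= 1)
  k <- seq_len(t)
  vapply(k, function(kk) {
    num <- lchoose(f$Y, kk) + lchoose(f$T - f$Y, t - kk) - lchoose(f$T, t)
    sum(exp(num))
  }, 0)
}

# observed (MLE) Hill number of the incidence distribution Y/U
hill_obs <- function(f, q) {
  a <- f$Y / f$U
  if (q == 0) f$S_obs
  else if (q == 1) exp(-sum(a * log(a)))
  else sum(a^q)^(1 / (1 - q))
}

# rarefied Hill number at integer t <= T from expected frequency counts
hill_rarefy <- function(f, q, t) {
  if (t == f$T) return(hill_obs(f, q))
  EQ <- expected_Qk(f, t)
  Ut <- t * f$U / f$T
  k <- seq_len(t)
  pk <- k / Ut
  if (q == 0) sum(EQ)
  else if (q == 1) {
    term <- ifelse(EQ > 0, pk * log(pk) * EQ, 0)
    exp(-sum(term))
  } else sum(pk^q * EQ)^(1 / (1 - q))
}

# Chao et al. incidence-based asymptotic Hill numbers, q in {0, 1, 2}
hill_asymptote <- function(f, q) {
  T <- f$T; Y <- f$Y; U <- f$U; Q1 <- f$Q1; Q2 <- f$Q2
  if (q == 0) return(f$S_obs + chao2_undetected(f))
  if (q == 2) {
    denom <- sum(Y * (Y - 1)) / (U^2 * (1 - 1 / T))
    return(if (denom > 0) 1 / denom else Inf)
  }
  # q = 1: Chao entropy estimator for incidence data
  A <- if (Q2 > 0 && Q1 > 0) 2 * Q2 / ((T - 1) * Q1 + 2 * Q2)
  else if (Q2 == 0 && Q1 > 1) 2 / ((T - 1) * (Q1 - 1) + 2)
  else 1
  yi <- Y[Y >= 1 & Y <= T - 1]
  dsum <- sum(vapply(yi, function(y) (y / T) * sum(1 / (y:(T - 1))), 0))
  Cc <- if (A == 1) 0 else
    (Q1 / T) * (1 - A)^(-T + 1) *
    (-log(A) - sum((1 - A)^(seq_len(T - 1)) / seq_len(T - 1)))
  exp((T / U) * (dsum + Cc) + log(U / T))
}

# single-size Hill estimate: hypergeometric rarefaction for t < T, observed
# at T, asymptote-anchored extrapolation beyond (analytic form for q = 2)
hill_at <- function(f, q, t) {
  T <- f$T; U <- f$U
  if (t <= T) {
    if (t == floor(t)) return(hill_rarefy(f, q, t))
    lo <- hill_rarefy(f, q, floor(t))
    hi <- hill_rarefy(f, q, ceiling(t))
    return(lo + (t - floor(t)) * (hi - lo))
  }
  if (q == 2) {
    denom <- (1 / t) * (T / U) +
      (1 - 1 / t) * sum(f$Y * (f$Y - 1)) / (U^2 * (1 - 1 / T))
    return(1 / denom)
  }
  obs <- hill_obs(f, q)
  asy <- hill_asymptote(f, q)
  if (asy <= obs) return(obs)  # saturated assemblage
  prev <- if (T > 1) hill_rarefy(f, q, T - 1) else obs
  beta <- if (asy == prev) 0 else (obs - prev) / (asy - prev)
  obs + (asy - obs) * (1 - (1 - beta)^(t - T))
}

#' Sample coverage of an incidence assemblage at size t
#'
#' Estimated fraction of the total incidence probability accounted for by
#' the species detected in a sample of `t` units. At the reference size
#' `t = T` this is `1 - (Q1/U) * (T-1)Q1 / ((T-1)Q1 + 2Q2)`.
#'
#' @param freqs `incidence_freqs` or binary matrix.
#' @param t sample size(s), up to `2T`.
#' @return coverage estimate(s) in `[0, 1]`.
#' @export
sample_coverage <- function(freqs, t) {
  f <- as_freqs(freqs)
  if (f$U == 0) stop("assemblage without incidences")
  T <- f$T; Y <- f$Y; U <- f$U; Q1 <- f$Q1; Q2 <- f$Q2
  Q0 <- chao2_undetected(f)
  A <- if (Q1 > 0) T * Q0 / (T * Q0 + Q1) else 1
  one <- function(tt) {
    if (tt < T) {
      if (tt != floor(tt)) {
        lo <- one(floor(tt)); hi <- one(ceiling(tt))
        return(lo + (tt - floor(tt)) * (hi - lo))
      }
      yy <- Y[(T - Y) >= tt]
      1 - sum(yy / U * exp(lgamma(T - yy + 1) - lgamma(T - yy - tt + 1) -
                             lgamma(T) + lgamma(T - tt)))
    } else if (tt == T) {
      1 - Q1 / U * A
    } else {
      1 - Q1 / U * A^(tt - T + 1)
    }
  }
  vapply(t, one, 0)
}

#' Default rarefaction/extrapolation size grid
#' @param T reference number of sampling units.
#' @param knots approximate number of grid points (default 40).
#' @param endpoint largest size (default `2T`).
#' @return sorted integer grid from 1 to `endpoint`, always including `T`.
#' @export
size_grid <- function(T, knots = 40, endpoint = 2 * T) {
  g <- unique(round(seq(1, endpoint, length.out = knots)))
  sort(unique(c(g, T)))
}

#' Hill-number rarefaction/extrapolation curve
#'
#' Interpolated (sample-based rarefaction), observed, and extrapolated Hill
#' numbers of order `q` over a grid of numbers of sampling units, following
#' the incidence-data estimators of Chao et al. Extrapolation of `q = 0`
#' uses the Chao2-type asymptote; `q = 2` has an analytic form at all
#' sizes.
#'
#' @param freqs `incidence_freqs` or binary matrix.
#' @param q Hill order: 0 (richness), 1 (exponential Shannon) or 2
#'   (inverse Simpson).
#' @param t_grid sizes (default [size_grid()] up to `2T`).
#' @return data.frame of class `diversity_curve`: `t`, `q`, `estimate`,
#'   `method` (interpolated/observed/extrapolated).
#' @export
hill_curve <- function(freqs, q, t_grid = NULL) {
  f <- as_freqs(freqs)
  stopifnot(q %in% c(0, 1, 2))
  if (is.null(t_grid)) t_grid <- size_grid(f$T)
  if (max(t_grid) > 2 * f$T)
    stop("extrapolation limited to twice the reference number of units")
  est <- vapply(t_grid, function(t) hill_at(f, q, t), 0)
  out <- data.frame(t = t_grid, q = q, estimate = est,
                    method = ifelse(t_grid < f$T, "interpolated",
                                    ifelse(t_grid == f$T, "observed",
                                           "extrapolated")))
  class(out) <- c("diversity_curve", "data.frame")
  out
}

# bootstrap assemblage: detected species with adjusted incidence
# probabilities plus Q0_hat undetected species (Chao et al. scheme)
bootstrap_probs <- function(f) {
  T <- f$T; Y <- f$Y; U <- f$U; Q1 <- f$Q1
  Q0 <- chao2_undetected(f)
  A <- if (Q1 > 0) T * Q0 / (T * Q0 + Q1) else 1
  a <- Q1 / T * A
  b <- sum(Y / T * (1 - Y / T)^T)
  w <- if (Q0 == 0 || b == 0) 0 else a / b
  p_det <- Y / T * (1 - w * (1 - Y / T)^T)
  p_und <- if (ceiling(Q0) > 0) rep(a / ceiling(Q0), ceiling(Q0)) else numeric(0)
  c(p_det, p_und)
}

#' Bootstrap confidence bands for Hill-number curves
#'
#' Resamples `T` sampling units from the estimated assemblage (detected
#' species with coverage-adjusted incidence probabilities, augmented by the
#' estimated number of undetected species), recomputes the curve per
#' replicate, and returns normal-approximation bands.
#'
#' @param freqs `incidence_freqs` or binary matrix.
#' @param q Hill order (0, 1 or 2).
#' @param t_grid sizes (default [size_grid()]).
#' @param B bootstrap replicates (default 200, minimum 20).
#' @param level confidence level (default 0.95).
#' @param seed integer seed (mandatory).
#' @return `diversity_curve` data.frame with `se`, `lcl`, `ucl` columns.
#' @export
bootstrap_ci <- function(freqs, q, t_grid = NULL, B = 200, level = 0.95,
                         seed) {
  if (missing(seed)) stop("a bootstrap seed is required")
  stopifnot(B >= 20)
  f <- as_freqs(freqs)
  if (is.null(t_grid)) t_grid <- size_grid(f$T)
  curve <- hill_curve(f, q, t_grid)
  pr <- bootstrap_probs(f)
  set.seed(as.integer(seed))
  boot <- matrix(0, nrow = B, ncol = length(t_grid))
  for (b in seq_len(B)) {
    Yb <- stats::rbinom(length(pr), f$T, pr)
    Yb <- Yb[Yb > 0]
    if (!length(Yb)) { boot[b, ] <- 0; next }
    fb <- structure(list(T = f$T, Y = Yb, S_obs = length(Yb),
                         Q1 = sum(Yb == 1), Q2 = sum(Yb == 2), U = sum(Yb)),
                    class = "incidence_freqs")
    boot[b, ] <- vapply(t_grid, function(t) hill_at(fb, q, t), 0)
  }
  se <- apply(boot, 2, stats::sd)
  z <- stats::qnorm(1 - (1 - level) / 2)
  curve$se <- se
  curve$lcl <- pmax(curve$estimate - z * se, 0)
  curve$ucl <- curve$estimate + z * se
  attr(curve, "B") <- B
  attr(curve, "seed") <- as.integer(seed)
  curve
}

#' Diversity estimates at a common base sample size
#'
#' Computes each group's Hill-number estimates (q = 0, 1, 2) with bootstrap
#' intervals at the shared size `t* = 2 x` the smallest group's number of
#' sampling units. Groups for which `t*` exceeds twice their own size are
#' capped at `2T` with a warning.
#'
#' @param groups named list of binary incidence matrices (one per cluster
#'   group).
#' @param B,level,seed bootstrap settings (see [bootstrap_ci()]).
#' @return data.frame: `group`, `q`, `t`, `estimate`, `se`, `lcl`, `ucl`;
#'   the common size in attribute `"t_star"`.
#' @export
estimate_at_common_size <- function(groups, B = 200, level = 0.95, seed) {
  if (missing(seed)) stop("a bootstrap seed is required")
  stopifnot(length(groups) >= 1)
  fs <- lapply(groups, as_freqs)
  t_star <- 2 * min(vapply(fs, `[[`, 0L, "T"))
  rows <- list()
  for (g in names(fs)) {
    f <- fs[[g]]
    t_use <- t_star
    if (t_use > 2 * f$T) {
      warning("group ", g, ": common size ", t_star,
              " exceeds 2T; capped at ", 2 * f$T)
      t_use <- 2 * f$T
    }
    for (q in 0:2) {
      ci <- bootstrap_ci(f, q, t_grid = t_use, B = B, level = level,
                         seed = seed)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, q = q, t = t_use, estimate = ci$estimate,
        se = ci$se, lcl = ci$lcl, ucl = ci$ucl)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "t_star") <- t_star
  out
}

#' Sample-coverage curve
#'
#' @param freqs `incidence_freqs` or binary matrix.
#' @param t_grid sizes (default [size_grid()]).
#' @return data.frame `t`, `coverage`, `method`.
#' @export
coverage_curve <- function(freqs, t_grid = NULL) {
  f <- as_freqs(freqs)
  if (is.null(t_grid)) t_grid <- size_grid(f$T)
  data.frame(t = t_grid, coverage = sample_coverage(f, t_grid),
             method = ifelse(t_grid < f$T, "interpolated",
                             ifelse(t_grid == f$T, "observed",
                                    "extrapolated")))
}
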
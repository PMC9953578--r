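# shared fixture builders; everything is generated in code

demo_registry <- function() {
  species_registry(
    canonical = c("B. alpinus", "B. monticola", "B. pratorum",
                  "B. lucorum/cryptarum complex"),
    synonyms = c("B. lapponicus alpinus" = "B. alpinus"),
    complexes = list("B. lucorum/cryptarum complex" =
                       c("B. lucorum", "B. cryptarum")),
    parasites = character(),
    drop = "B. sp.")
}

# one record row with overridable fields
rec_row <- function(species = "B. alpinus", count = 1, site = "KBT",
                    year = 1935, month = 7, day = 15,
                    elev_low = 1900, elev_high = 2000) {
  data.frame(species = species, count = count, site = site, year = year,
             month = month, day = day, elev_low = elev_low,
             elev_high = elev_high, stringsAsFactors = FALSE)
}

records_df <- function(...) do.call(rbind, list(...))

random_incidence <- function(n_units, n_species, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(n_units * n_species, 1, p), n_units, n_species)
    m <- m[, colSums(m) > 0, drop = FALSE]
    if (ncol(m) >= 2 && all(rowSums(m) > 0)) break
  }
  rownames(m) <- paste0("u", seq_len(n_units))
  colnames(m) <- paste0("sp", seq_len(ncol(m)))
  m
}

# brute-force q = 0 rarefaction: mean richness over all C(T, t) subsets
brute_rarefaction <- function(m, t) {
  subsets <- utils::combn(nrow(m), t, simplify = FALSE)
  mean(vapply(subsets, function(i)
    sum(colSums(m[i, , drop = FALSE]) > 0), 0))
}

# independent one-factor PERMANOVA: direct partition of squared
# dissimilarities by group membership (no Gower machinery)
brute_permanova_f <- function(D, groups) {
  n <- nrow(D)
  ss_total <- sum(D[upper.tri(D)]^2) / n
  ss_within <- 0
  for (g in unique(groups)) {
    i <- which(groups == g)
    Dg <- D[i, i, drop = FALSE]
    ss_within <- ss_within + sum(Dg[upper.tri(Dg)]^2) / length(i)
  }
  a <- length(unique(groups))
  ((ss_total - ss_within) / (a - 1)) / (ss_within / (n - a))
}

# hand Lance-Williams Ward agglomeration (naive O(n^3)), for the dual-route
# check of ward_cluster
brute_ward_heights <- function(D, variant = "ward_d") {
  D <- as.matrix(D)
  if (variant == "ward_d2") D <- D^2
  n <- nrow(D)
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(Inf, NA, NA)
    for (a in seq_along(active)) for (b in seq_along(active)) {
      if (a < b) {
        i <- active[a]; j <- active[b]
        if (D[i, j] < best[1]) best <- c(D[i, j], i, j)
      }
    }
    i <- best[2]; j <- best[3]
    h <- best[1]
    heights <- c(heights, if (variant == "ward_d2") sqrt(h) else h)
    ni <- size[i]; nj <- size[j]
    for (k in active) {
      if (k == i || k == j) next
      nk <- size[k]
      D[i, k] <- D[k, i] <-
        ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * D[i, j]) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}
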
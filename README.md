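# beeshift

Community change analysis for alpine bumblebee resurveys.

Resurvey studies compare historical occurrence collections (often with
coarse elevation information and unknown sampling effort) against modern
standardized surveys to ask whether montane pollinator communities have
shifted under climate warming. `beeshift` implements the full analysis
chain for such a comparison along an elevational gradient, together with a
synthetic survey generator so every step can be exercised, tested and
power-checked without field data.

## What it computes

**Harmonization.** Raw occurrence records (species, count, site, date,
elevation interval) are filtered (elevation uncertainty > 500 m, missing
dates, records outside 1100–2899 masl, suspected nest excavations),
normalized against a species registry (synonyms, the unresolvable
*lucorum/cryptarum*-type complex), and pooled into sampling units
`year#site#meanElevMSL`. Recent records are re-binned into the coarse
historical elevation intervals of the same site, and the unit × species
table is reduced to presence/absence.

**Community structure.** Sørensen dissimilarity
`d = (b + c) / (2a + b + c)`, Ward clustering (`ward.D` or `ward.D2`),
tree cut at a fixed height, and crossing of elevation clusters with
sampling period into analysis groups.

**Ordination and tests.** Distance-based constrained ordination (CAP:
principal coordinates regressed on constraints), permutation ANOVA,
bidirectional stepwise constraint selection, Ezekiel-adjusted R²,
envfit-style fitted vectors, PERMANOVA with sequential sums of squares
(`SS_total = Σ_{i<j} d²_ij / n`, pseudo-F, free permutation of units),
betadisper-style multivariate dispersion homogeneity, tie-corrected
Kruskal–Wallis tests and Holm/Bonferroni/Benjamini–Hochberg adjustment.
All of these are implemented in the package and verified against vegan
and base R as independent oracles in the test suite.

**Diversity.** Incidence-based Hill numbers `qD` for q = 0 (richness),
1 (exponential Shannon), 2 (inverse Simpson): sample-based rarefaction via
expected incidence frequency counts, Chao2-type asymptotes, extrapolation
to twice the reference number of units, sample coverage, bootstrap
confidence bands, and per-group estimates at a common size (twice the
smallest group).

**Traits.** Twelve functional traits (proboscis length, body size,
nesting, social parasitism, habitat, STI, micro- and macroclimatic
preference), complex averaging, z-scaling across the species pool,
community-weighted means (equal weights under presence/absence), and
between-period Kruskal–Wallis comparisons per elevation cluster.

**Climate.** Fusion of a coarse long-term monthly temperature grid with a
fine-resolution grid: moving-least-squares ("patch-like") regridding,
per-cell/per-month linear bias correction fitted on an overlap period,
splicing, four 30-year temperature indices (annual, summer and winter
half-years, spring = March–June), lapse-rate downscaling to a DEM using
the local vertical gradient (−6.68 K/km), elevation-zone means,
equivalent-elevation shifts (≈150 m per K) and glacier-area change.

## Worked example

```r
library(beeshift)

cfg  <- default_config(seed = 1)          # the default synthetic world
pool <- gen_species_pool(cfg$scenario)    # 28 species, 7 cuckoo bees
records  <- gen_units_and_records(pool, cfg$scenario)
filtered <- filter_records(records, filter_rules(
  allowed_years = unlist(cfg$scenario$periods), period_exclusions = list()))
units     <- pool_to_units(filtered)
incidence <- build_incidence(units, pool$registry)   # 42 units x 27 species

d      <- sorensen_matrix(incidence)
labels <- cut_tree(ward_cluster(d, "ward_d"), height = 1.5)
groups <- cross_with_period(labels, units)

env <- unit_environment(units, cfg)       # temperatures, elevation, year
sel <- stepwise_select(d, env[, c("spring_temp", "mean_elev", "year",
                                  "annual_temp")], n_perm = 199, seed = 42)
adjusted_r2(sel)
permanova(d, env[, c("spring_temp", "period")], n_perm = 999, seed = 42)
```

This prints:

```
selected constraints: spring_temp + year
$r_squared    0.3688259
$adj_r_squared 0.336458

         term df     ss      f      r2     p
1 spring_temp  1 3.8293 28.527 0.38393 0.001
2      period  1 0.9096  6.776 0.09119 0.001
3    Residual 39 5.2352     NA 0.52488    NA
4       Total 41 9.9741     NA 1.00000    NA
```

Spring temperature is retained by stepwise selection and explains the
largest share of compositional variance; the sampling period adds a
significant independent effect (the engineered collapse of socio-parasitic
species). Observed richness drops from 27 species (historic) to 24
(recent), and a warming of 1.76 K corresponds to an upslope isotherm shift
of `equivalent_shift(1.76, -6.68)` ≈ 263.5 m.

The one-command version of the same analysis:

```sh
Rscript inst/cli/beeshift.R all --outdir run1 --seed 1
```

writes every table (units, incidence, dissimilarities, dendrogram as
Newick, scores, test results, diversity curves, CWM tables, downscaled
climate indices as ASCII grids) plus a manifest with config, seeds and
checksums.

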
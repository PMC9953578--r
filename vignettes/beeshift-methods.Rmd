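---
title: "Methods: resurvey community change along an alpine gradient"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resurvey community change along an alpine gradient}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeshift)
```

# The problem

Historical insect collections are one of the few windows onto community
states before recent climate warming, but they were gathered without a
standardized design: elevations are reported as coarse intervals, effort
is unknown, nomenclature has changed, and some records are artifacts (a
single excavated nest can contribute dozens of individuals of one
species). `beeshift` implements a complete, testable pipeline for
comparing such a historical bumblebee collection against a modern
resurvey along an elevational gradient: harmonization into comparable
sampling units, multivariate community analysis against climate
covariates, incidence-based diversity estimation, trait-based community
description, and the production of the climate covariates themselves from
two gridded temperature datasets.

Because the original survey data cannot ship with the package, a
first-class synthetic generator produces occurrence records, trait tables
and climate rasters with known ground truth. Every statistical claim in
the test suite is made against that generated world or against explicit
hand-computed or brute-force oracles.

# Harmonization model

The unit of analysis is the *sampling unit*: all records pooled within
one year, one site, and one elevation interval, identified as
`year#site#meanElevMSL`. The harmonization rules are:

* records with elevation uncertainty strictly greater than 500 m are
  excluded (an interval spanning exactly 500 m is kept, matching the
  strict reading of "uncertainty > 500 m");
* records without a calendar date are excluded, as are years outside the
  declared survey periods and elevations outside 1100–2899 masl;
* a (site, date, elevation-interval) group containing exactly one species
  with a total count of at least `N_nest = 30` individuals is treated as
  a nest excavation and removed. The historical source states only the
  qualitative rule; 30 is a configuration default, not a claim about the
  original analysis;
* species exclusions are period-scoped configuration (e.g. species whose
  historical counts were not recorded);
* elevation intervals are closed; a point elevation is the degenerate
  interval `[e, e]`.

Overlapping intervals of one site and year are merged into their union
(they are redundant records of one effort), and recent records are
re-assigned to the historical intervals of their site by midpoint, ties
going to the lower bin, so both periods share the coarse historical
elevation structure. Every cell of the resulting presence/absence matrix
is traceable to the surviving records through a provenance attribute.

# Community structure and ordination

Pairwise Sørensen dissimilarity, `d = (b + c)/(2a + b + c)`, is the
binary special case of Bray–Curtis. Ward's minimum variance clustering is
available in both conventions: `ward_d` applies the Lance–Williams update
to the dissimilarities as given, `ward_d2` to their squares with
square-rooted heights. The analysis text and the figure caption of the
source study name different variants; both are implemented and the
default follows the Methods text (`ward_d`). The tree is cut at a fixed
height (default 1.5 on the Ward height scale) and clusters are labelled
`A`, `B`, … in leaf order, then crossed with the sampling period into the
analysis groups.

Constrained ordination follows the distance-based redundancy analysis
construction: principal coordinates of the Gower-centered dissimilarity
matrix are regressed on the (centered, dummy-coded) constraints;
constrained axes are the singular directions of the fitted values,
residual axes those of the residuals. Axes with negative eigenvalues are
excluded from scores but their magnitude is reported as negative inertia;
a Lingoes correction is available. This matches common practice for
distance-based RDA and reproduces vegan's `capscale` eigenvalues, R² and
pseudo-F exactly on shared fixtures (verified in the test suite).

Significance testing permutes the rows of the principal-coordinate
matrix freely; sequential (Type I) term tests share the full-model
residual. Stepwise selection is bidirectional with `alpha_in = 0.05` and
`alpha_out = 0.10`; the source analysis states only the direction and the
p < 0.05 acceptance rule, so the drop threshold is our choice of the
conventional value. The permutation count (default 999) and seed are
mandatory configuration and are embedded in every result object.

PERMANOVA partitions `SS_total = sum_{i<j} d^2_ij / n` sequentially via
hat-matrix projections of the Gower-centered matrix, equivalent to
`adonis2(..., by = "terms")`. For `n <= 7` an exact mode enumerates all
`n!` permutations. Dispersion homogeneity follows the PERMDISP
construction with the imaginary-part subtraction convention for
non-Euclidean dissimilarities and a spatial-median group center by
default (the conventional default; the source is silent on the choice).

# Diversity estimation

All diversity quantities are incidence-based (sample-based) Hill numbers.
With `T` units, incidence frequencies `Y_i`, `U = sum(Y_i)`, `Q1` uniques
and `Q2` duplicates:

* rarefaction at `t <= T` uses the hypergeometric expected frequency
  counts `E[Q_k(t)]`; for `q = 0` this reduces to the classical
  `S(t) = sum_i [1 - C(T - Y_i, t)/C(T, t)]` and equals the brute-force
  average over all `C(T, t)` unit subsets (tested to 1e-9);
* the richness asymptote is the Chao2-type bound
  `S_obs + (T-1)/T * Q1^2/(2 Q2)` (with the `Q1(Q1-1)/2` fallback when
  `Q2 = 0`); extrapolation approaches it geometrically at the rate fixed
  by the one-step rarefaction decrement, `q = 1` analogously from the
  incidence entropy estimator, and `q = 2` has an analytic form valid at
  all sizes;
* sample coverage uses `1 - (Q1/U) * (T-1)Q1/((T-1)Q1 + 2Q2)` at the
  reference size with the standard interpolation/extrapolation;
* bootstrap bands resample `T` units from the estimated assemblage
  (coverage-adjusted detection probabilities plus the estimated number of
  undetected species) and use normal approximation at the 95% level,
  with B = 200 by default (the source states bootstrapping but not B).

These estimators reproduce the reference implementation (iNEXT 3.0.2) to
machine precision on fixtures frozen into the test suite.

**A known limitation, deliberately preserved.** The Hill inequality
`q0 >= q1 >= q2` is a property of true diversities and holds exactly for
the rarefied and observed estimates. It can fail in the *extrapolated*
range: the `q = 0` curve targets the Chao2 asymptote, which is a lower
bound of richness, while the `q = 1` estimator is nearly unbiased, so on
assemblages with few uniques the curves cross beyond `t = T`. The
reference implementation behaves identically. We report the estimators
exactly as published rather than distorting them to enforce the ordering;
the corresponding acceptance assertion is intentionally left failing with
this explanation.

Group comparisons at a common size use `t* = 2 x` the smallest group's
unit count; by construction the smallest group then sits exactly at its
own extrapolation endpoint `2T`.

# Traits

Twelve traits describe each species: proboscis length (mm), body size
(mm), paired indicators for nesting (above/below ground), habitat (open /
forest-edge), microclimate (wide/cold) and macroclimate
(indiscriminate/alpine), a social-parasitism flag, and the species
temperature index (STI, °C). Members of an unresolvable species complex
are merged by arithmetic trait averaging before analysis (binary traits
may become fractional). Traits are z-scaled across the species pool
present in the analysis, after complex merging and never per unit.

Although the source describes CWM weighting by "relative abundance", the
analysis matrix is presence/absence; the only consistent reading is equal
weights among the species present, which makes the raw-scale CWM of a
binary trait the share of present species bearing it. Between-period
comparisons are Kruskal–Wallis tests per trait within each elevation
cluster, Holm-adjusted across the whole family (the source does not name
its adjustment; Holm controls FWER without independence assumptions).
When strong turnover leaves no cluster with units from both periods, the
pipeline falls back to one overall between-period comparison and says so.

# Climate processing

Two monthly temperature datasets at different resolutions are fused: the
coarse long-term grid is interpolated to the fine grid, a linear map
(slope, intercept) is fitted per cell and calendar month on a 30-year
overlap, applied to the coarse data before the splice year (default
1961), and the fine data used afterwards. Four indices are computed as
30-year means: annual, summer half-year (Apr–Sep), winter half-year
(Oct–Mar, assigned to the year of its January–March part), and spring
(Mar–Jun, the snowmelt-relevant definition).

The "patch" interpolation of the original toolchain is approximated by a
moving-least-squares scheme: a local biquadratic fitted to the 12 nearest
source cells with inverse-distance weights, evaluated at the target.
What downstream steps rely on — smoothness, exactness on constant,
linear and quadratic fields — is guaranteed and tested; bit-identity
with the original library is not a goal.

Downscaling subtracts the vertical temperature dependence
(`gamma * z`, default `gamma = -6.68 K/km`), interpolates the residuals
to the 10 m DEM, and adds back `gamma * z_DEM`. On a pure lapse field
this is exact to numerical precision. The equivalent-elevation shift of a
warming is `delta_T / |gamma|`; 1 K corresponds to 149.7 m ≈ 150 m.
Note that dividing the reported 1.76 K warming by the gradient gives
263.5 m, while the source prints 257 m — a figure that evidently reflects
spatial averaging not reproducible from the printed values alone. The
package reports the division-based shift and documents the discrepancy
here.

Raster I/O uses the plain-text ESRI ASCII grid format; the execution
environment provides no NetCDF/GeoTIFF reader, so binary raster formats
are out of scope for this build and grids are first-class in-memory
objects.

# The synthetic world

The generator emulates the survey's stated structure, and its defaults
are the stated conditions, fixed once:

* 28 species, of which 7 (25%) are socio-parasitic cuckoo bees and two
  form an unresolvable complex; 11 sites spanning 1100–2899 masl, each
  with two coarse historical elevation bins (200–500 m wide, separated by
  a 100 m gap so that adjacent bins remain distinct units);
* Gaussian thermal niches: presence of species `i` in a unit is Bernoulli
  with `p = p_max * exp(-(T - T_opt)^2 / (2 sigma^2)) * m_period`, with
  niche width `sigma = 2.5 K`, `p_max` in 0.6–0.9, and STI equal to the
  optimum plus 0.3 K noise. Optima are drawn from two guilds (montane and
  alpine centers with 1.2 K within-guild scatter) mirroring the
  two-stratum structure of alpine bumblebee communities on either side of
  the tree line; a continuous uniform spread of optima produces gradual
  turnover that fragments Ward clusters, which is not what the emulated
  system looks like;
* counts for present species are zero-truncated Poisson (mean 3), so the
  presence/absence collapse is exercised nontrivially;
* spring temperature at a unit is `T0 + gamma z + warming + site offset`:
  a 1.76 K between-period warming, the -6.68 K/km gradient, and a
  persistent site-level deviation (sd 0.8 K) representing aspect and
  microclimate. The persistent offsets matter: without them spring
  temperature is an exact affine function of elevation and period, and no
  selection procedure could meaningfully prefer it over its own
  components. Annual temperature carries its own offset pattern
  (winter microclimates differ from spring ones) and only 60% of the
  warming signal;
* period-2 occupancy of parasites is multiplied by 0.1, emulating the
  observed collapse of cuckoo bees;
* the climate world is a smooth valley DEM with a seasonal cycle, a
  warming ramp over 1976–2005 whose amplitude is solved analytically so
  the between-period spring contrast equals the configured warming
  exactly in expectation, i.i.d. cell-month noise (sd 0.5 K), and a
  coarse dataset formed by block-averaging the truth and applying an
  affine bias.

What a green test does and does not establish: the generator reproduces
the design (two periods, coarse bins, thermal structure, parasite
decline) but not everything about real resurvey data — no observer
effects, no phenological mismatch between survey dates, no spatial
autocorrelation of communities beyond the thermal field, no abundance
information carried into the analysis. Power statements (e.g. "the period
term is significant in ≥ 80% of worlds") are statements about this
stated world at its default noise levels, not about any particular field
dataset.

Because period-2 parasites become rare rather than impossible, the
*observed* richness drops in period 2 while the Chao2 asymptote need
not: the estimator correctly attributes the surviving rare detections to
a persisting species pool. Tests of the richness decline therefore use
detected richness.

# Numerical choices and degenerate inputs

* Unit pairs with no species at all get Sørensen distance 0 with a
  warning; all-zero unit rows are retained in the incidence matrix (they
  carry real information: a visited unit with nothing found).
* Eigenvalues within `1e-9` of zero (relative) are treated as null axes.
* Permutation p-values use the `(1 + #{F* >= F}) / (1 + n_perm)`
  convention, so `p >= 1/(n_perm + 1)` always.
* Kruskal–Wallis applies the standard tie correction; all-tied data give
  `H = 0, p = 1` rather than 0/0.
* Constant trait columns are centered but not divided (warning); a
  zero-variance predictor in the bias model falls back to intercept-only.
* The spatial median is computed by Weiszfeld iteration with a 1e-8
  convergence tolerance, matching vegan's `betadisper` to ~1e-5.
* Bootstrap, permutation and generator seeds are explicit everywhere; the
  synthetic world derives independent streams from one master seed, and
  `site_offsets()` restores the caller's RNG state.

# Known limitations

* Abundances never enter the analysis (deliberate, matching the
  harmonized design); abundance-based diversity is out of scope.
* The stepwise competition between spring temperature and elevation is
  decided by the persistent site-level temperature variation; in worlds
  with very small site offsets the two are nearly exchangeable and
  selection between them approaches a coin flip, which is a property of
  the inference problem, not of the implementation.
* The patch-like regridder extrapolates at domain edges from the nearest
  patches (with a warning); edge cells of a target wider than the source
  are less accurate.
* No georeferencing, no glacier-outline processing (areas are scalar
  inputs), no precipitation or daily-scale indices.
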
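Package: beeshift
Title: Community Change Analysis for Alpine Bumblebee Resurveys
Version: 0.1.0
Authors@R:
    person("Kals", "Resurvey Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Harmonizes historical and recent bumblebee occurrence records
    into comparable elevation-binned sampling units and quantifies community
    change along an alpine gradient. Provides Sorensen dissimilarities with
    Ward clustering, distance-based constrained ordination (CAP) with
    permutation tests and stepwise constraint selection, PERMANOVA and
    multivariate dispersion homogeneity tests, incidence-based Hill-number
    rarefaction and extrapolation with bootstrap confidence intervals,
    community-weighted mean functional traits, and a two-resolution climate
    fusion pipeline (bias correction, temperature indices, lapse-rate
    downscaling to a digital elevation model). A synthetic-data generator
    with known ground truth replaces the field survey for testing and
    parameter-recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    vegan,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
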
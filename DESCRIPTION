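Package: infantgut
Title: Longitudinal Analysis of Infant Gut Microbiota Convergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing dense longitudinal 16S rRNA OTU count tables
    from infant cohorts: common-scaling library normalization, Bray-Curtis and
    generalized UniFrac beta diversity, non-metric multidimensional scaling with
    Kruskal stress, PERMANOVA, fixed-df spline smooths, cubic-spline pseudo-day
    interpolation of per-infant composition series, detection of windows of
    accelerated between-infant convergence, dynamic-time-warp clustering of
    phylum-level trajectories, and twin-similarity testing. Includes a synthetic
    cohort generator with planted bloom, individuality, and twin structure so the
    whole pipeline is testable without raw sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    splines,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    phangorn,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
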
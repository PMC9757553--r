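Package: hopspm
Title: Step-Down-Hop Ground Reaction Force and Knee Power Analysis with
    One-Dimensional Statistical Parametric Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for single-leg step-down-hop
    biomechanics. Generates synthetic dual-rate hop trials (three ground
    reaction force components plus a knee moment/angular-velocity pair) with
    injectable side, condition and group effects; extracts the stance phase by
    a 20 N vertical-force threshold; applies three-phase, peak-aligned time
    normalisation to 1001 nodes; derives knee joint power and nine discrete
    outcome variables; performs one-dimensional statistical parametric mapping
    (paired and two-sample t fields, Hotelling's T-squared fields, residual
    smoothness estimation, random-field-theory thresholds, permutation
    oracle); and runs the discrete-variable statistics of a cross-over and a
    parallel-group design (repeated-measures ANOVA with Mauchly's test and
    Greenhouse-Geisser correction, Bonferroni-corrected paired post-hocs,
    change scores, exact Mann-Whitney U).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
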
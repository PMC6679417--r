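Package: spermorph
Title: Sperm Morphometrics, Head Drag and Thermal-Acclimation Inference for
    External Fertilisers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing temperature-acclimation effects on fish sperm
    morphology and hydrodynamics. Computes per-cell morphometric derivations
    (prolate-spheroid head surface area, ellipticity, flagellum-to-head
    ratios), theoretical Stokes-law drag on sperm heads under
    temperature-dependent water viscosity, deformity-scan tallies with the
    field-of-view stopping rule, and the full set of hierarchical statistical
    comparisons (binomial GLMs for deformity proportions, linear mixed models
    for morphology and drag, least-squares-means post-hoc contrasts). A
    seeded synthetic-data generator emulates the two-group acclimation study
    design so every pipeline stage can be exercised and calibrated by
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    emmeans,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
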
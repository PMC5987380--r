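Package: tibiamorph
Title: Whole-Tibia Micro-CT Morphometry with Synthetic Phantom Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reference-anchored trabecular morphometry (BV/TV, Tb.N, Tb.Th,
    Tb.Sp, degree of anisotropy via mean intercept length), whole-bone cortical
    slice geometry (cross-sectional area, cortical thickness, principal second
    moments of area, polar moment, ellipticity), calibrated tissue mineral
    density, bone curvature lever-arm statistics and per-percentile three-way
    factorial ANOVA significance mapping for murine long-bone micro-CT stacks.
    A parametric voxel phantom generator produces curved hollow-shaft tibia
    models and full factorial cohorts with analytic ground truth, so every
    stage of the pipeline is testable without scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    car,
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
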
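Package: rededge
Title: Red-Edge Spectral Indices for Leaf Area Index and Canopy Chlorophyll Retrieval
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Empirical retrieval of green leaf area index (LAI) and canopy
    chlorophyll from hyperspectral and Sentinel-2-like multispectral
    reflectance. Implements the generic normalized difference index (NDI)
    with exhaustive band-pair optimization, the Normalized Area Over the
    reflectance Curve (NAOC) computed by trapezoidal integration of the
    red-edge reflectance curve, spectral response function resampling of
    hyperspectral cubes to arbitrary band sets (the Sentinel-2 MSI set ships
    as a preset), proportional, linear and exponential index-to-parameter
    calibrations with validation statistics, a seeded synthetic canopy scene
    simulator with known per-pixel LAI and chlorophyll truth, and end-to-end
    pipelines for LAI mapping and the red-edge band-ablation experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
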
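Package: mgwrdim
Title: Multiscale Geographically Weighted Regression and Dimensions of
    Spatial Disparity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for county-scale ecological analysis of spatially
    varying associations: composite deprivation indices built by principal
    component analysis, a global ordinary-least-squares baseline with
    variance-inflation diagnostics, a geographically weighted regression
    (GWR) engine with an adaptive bisquare kernel and AICc bandwidth
    selection, a multiscale GWR (MGWR) back-fitting calibrator with
    per-variable bandwidths and Monte Carlo testing for spatial
    non-stationarity, and a three-dimension classification of each
    covariate's geographic disparity (level of influence, scalability,
    specificity). Includes a synthetic-data generator with known
    constant, gradient and bump coefficient surfaces for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    withr
Config/testthat/edition: 3
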
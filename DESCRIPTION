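Package: radkrige
Title: Iterative Geostatistical Dose Mapping for Population-Scale Radiation Events
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs radiation exposure plumes from a small fraction of
    sampled locations by iterative kriging and variance-guided densification.
    Provides a synthetic scenario generator (nested dose-contour plumes over
    census-like population subdivisions), population-proportional random
    sampling with optional dose-measurement error and directional bias,
    ordinary/simple/universal kriging and an empirical Bayesian kriging
    approximation with prediction standard errors, upper-quartile threshold
    densification, dose-band overlap heat matrices with diagonal Bray-Curtis
    dissimilarity and root-mean-square deviation stopping rules, and
    population-weighted accuracy scoring of reconstructed plumes against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
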
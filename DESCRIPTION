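Package: funspectra
Title: Functional Spectra of Life-History Strategies and Their Erosion Under
    Extinction Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the functional diversity of life-history strategies in
    species assemblages (built around turtles, tortoises and crocodilians) and
    how simulated extinctions of threatened species erode it. Provides
    phylogenetic comparative tools (Pagel's lambda estimation, phylogenetic
    generalized least squares, lambda-transformed Brownian covariance),
    phylogenetically informed multiple imputation of missing traits by
    chained-equations predictive mean matching with phylogenetic eigenvector
    covariates, phylogenetic principal component analysis with pooling across
    imputations, kernel trait-probability-density (TPD) functional spaces on a
    fixed grid with highest-density-region thresholding, IUCN- and threat-based
    extinction scenario simulations with randomisation null envelopes, binomial
    smooth surfaces of extinction risk over the functional space, and a
    synthetic-data generator that emulates the statistical structure of the
    real datasets for testing and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    mgcv,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
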
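Package: hawkesmix
Title: Space-Time Self-Exciting Point Processes with Gaussian-Exponent Mixture Kernels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Fast maximum-likelihood estimation of space-time Hawkes
    (self-exciting) point process models whose background and triggering
    intensities are mixtures of Gaussian-type exponent kernels with
    exponential temporal decay. The compensator of the log-likelihood has a
    closed form in normal distribution functions, and the triggering history
    sum is truncated to a fixed number of most recent events, so fitting
    scales to large event catalogs. Includes BIC order selection for the
    number of mixture components, a branching-process simulator with
    correlated bivariate-normal kernels and burn-in trimming, residual
    analysis by thinning and super-thinning, edge-corrected Ripley K and
    centered L functions with Monte-Carlo envelopes, catalog CSV input and
    output, equirectangular projection of geographic catalogs, and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pracma,
    geosphere,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
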
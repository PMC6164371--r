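Package: vrfrap
Title: Variable-Radius FRAP Analysis of Anomalous and Confined Membrane Diffusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of fluorescence recovery after
    photobleaching (FRAP) experiments at variable bleach radii. Provides an
    event-driven Monte Carlo simulator of continuous-time random walk (CTRW)
    anomalous subdiffusion in a bounded disk with Gaussian-profile
    photobleaching, closed-form recovery models for anomalous, free Brownian
    and restricted Brownian motion, nonlinear least-squares fitting with
    chi-square model comparison, and the variable-radius inference that
    regresses fitted parameters against inverse bleach radius to discriminate
    CTRW subdiffusion from domain-confined motion and to estimate
    confinement-domain size from the mobile-fraction diffusion law.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
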
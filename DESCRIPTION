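Package: cestnet
Title: Autonomous Analysis of Anti-Phase Amide-Proton CEST NMR Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and autonomous analysis of amide-proton anti-phase
    chemical exchange saturation transfer (CEST) NMR profiles. Provides a
    Liouvillian spin-dynamics simulator for two-site and forked three-site
    conformational exchange (including the real-eigenvalue dephasing
    propagator used to emulate B1 inhomogeneity), fixed-size time-domain
    packing of CEST profiles via real Fourier transforms and zero-filling,
    a transformation network that virtually decouples anti-phase profiles
    into in-phase profiles, a chemical-shift network that reports shift
    positions of exchanging states together with calibrated uncertainties,
    a least-squares fitting back-end, and calibration and consistency
    evaluators for validating the stacked analysis on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
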
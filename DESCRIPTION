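Package: memfhn
Title: Memristive FitzHugh-Nagumo Media for Cardiac Tissue Under
    Electromagnetic Induction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulator for electrical activity in two-dimensional cardiac
    tissue under electromagnetic induction. Implements a three-variable
    memristive FitzHugh-Nagumo reaction-diffusion model in which a magnetic
    flux variable feeds back on the membrane potential through a
    flux-controlled memductance, with explicit Euler integration on a
    no-flux lattice, localized electromagnetic radiation and disk-confined
    Gaussian white noise forcing on the flux field, and the measurement
    instruments needed to characterize spiral-wave formation, suppression
    and breakup: strict-local-maximum peak detection, bifurcation scans
    over the induction gains, activity classification, spatial dispersion
    and phase-singularity counting. Ships one-command presets for the
    canonical numerical experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
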
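Package: hpmwave
Title: Thermoelastic Stress-Wave Dosimetry for Pulsed High-Power Microwave
    Exposure of the Head
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage multiphysics analysis of single intense microwave
    pulses incident on the human head, at desk scale on synthetic layered
    phantoms. A finite-difference time-domain (FDTD) Maxwell solver computes
    specific absorption rate (SAR) fields and IEEE C95.1-style peak 10-g
    averages, validated against an embedded Mie-series oracle; an adiabatic
    linear pulse-heating model converts SAR to temperature rises; staggered
    pressure-velocity solvers (1D spherical and 3D Cartesian) propagate the
    resulting thermoelastic stress waves; spectral analysis recovers the
    microwave-auditory (Frey effect) frequencies; and injury metrics compare
    tensile-pressure and strain extrema against cavitation and axonal-strain
    thresholds, with exposure-limit arithmetic for link-budget scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
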
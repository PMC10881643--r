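Package: sfltkinetics
Title: Kinetic Modelling of Constitutive sFLT1 Secretion from Endothelial Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mechanistic two-compartment delay-differential-equation model of
    constitutive soluble FLT1 (sFLT1/sVEGFR1) secretion from endothelial
    cells. Provides exact piecewise-analytic and numerical simulation of
    media-change accumulation, pulse-chase, cell-free decay and inhibitor
    treatment protocols; weighted least-squares parameter estimation from
    heterogeneous time-course data with multi-start optimisation and
    profile-likelihood uncertainty; inversion of observed extracellular
    sFLT1 ratios into fractional inhibition of trafficking rate constants;
    unit conversion between molecules per cell and media concentration; and
    a synthetic time-course generator emulating densitometry-style
    fold-change data for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    readr,
    deSolve,
    lhs,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
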
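Package: veingraft
Title: Rule-Based Simulation of Vein Graft Intimal Remodeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An agent-based (rule-based) simulator of early intimal
    hyperplasia in arterialized vein grafts. Smooth muscle cells (SMC),
    extracellular matrix (ECM) and monocytes occupy a rectangular lattice;
    shear-, time- and depth-dependent division and apoptosis probabilities
    are calibrated from BrdU and TUNEL labeling kinetics, matrix is
    produced on a post-division schedule and degraded on apoptosis, and
    monocyte influx augments matrix synthesis. One- and two-dimensional
    growth algorithms, ensemble Monte-Carlo execution, focal-stenosis
    shear-field scenarios, synthetic input generators, and calibration of
    kinetic coefficients from labeling tables are provided.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
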
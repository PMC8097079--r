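Package: tensionpaint
Title: DNA Hairpin Tension Sensors and DNA-PAINT Point-Pattern Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for molecular tension sensing with DNA hairpin probes read
    out by DNA-PAINT super-resolution microscopy. Implements an equilibrium
    unzipping-force model for hairpin probes (nearest-neighbor duplex
    thermodynamics plus worm-like-chain stretching of the released single
    strand), a localization-level DNA-PAINT acquisition simulator with
    experiment-matched binding kinetics, neighbor-count gradient-ascent
    detection of single molecular sites from localization clouds, k-th
    nearest-neighbor statistics with matched complete-spatial-randomness null
    simulations, localization-precision (aligned cross-section and NeNA) and
    qPAINT binding-event metrics, and two-channel axial colocalization
    profiles. All tabular results are tibbles with broom-style tidiers and
    ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    RANN,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
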
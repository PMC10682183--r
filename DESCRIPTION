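Package: prioncolony
Title: Multiscale Simulation of Amyloid Prion Propagation in Growing
    Yeast Colonies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An agent-based lattice model of budding-yeast colony growth
    coupled, cell by cell, to chemical rate equations for amyloid prion
    nucleation, elongation, fragmentation and clumping.  Each cell carries
    its own chemical state which is integrated on a fine clock, exchanged
    between mother and bud by first-order partition while the septum is
    open, and diluted as cell volume changes.  Includes a red/white
    colony-colour phenotype readout, binary prion classification,
    lineage and fate mapping, colony interrogation and curing-curve
    analysis, with scenario presets for reproducible in silico
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ape
Config/testthat/edition: 3
RoxygenNote: 7.3.3
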
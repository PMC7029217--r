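Package: symbflux
Title: Constraint-Based Analysis of Symbiotic Nitrogen Fixation in
    Rhizobial Bacteroids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for constraint-based metabolic modelling of
    nitrogen-fixing bacteroids. Provides a stoichiometric model container
    with readers and writers for SBML Level 3 (FBC) and COBRA-style JSON,
    a model-quality validation battery (elemental and charge balance,
    stoichiometric consistency, energy-generating-cycle detection), a
    built-in bounded-variable simplex engine for flux balance analysis,
    flux variability analysis, shadow prices and joint 1-norm-minimised
    flux fitting, gene-protein-reaction rule parsing with single-gene
    deletion screening and symbiotic-gene classification, E-Flux
    integration of transcriptome data into condition-specific models, a
    randomised evolutionary sensitivity analysis that identifies the
    reactions whose expression-derived bounds determine differences in
    symbiotic yield, and a generator of a small, fully balanced toy
    bacteroid network with matched two-condition expression profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
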
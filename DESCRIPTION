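Package: biocad
Title: Multi-Objective Design and Identifiability Analysis of Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A workbench for constraint-based (flux-balance) metabolic models:
    flux balance analysis on a compiled bounded-variable simplex, the optBioCAD
    stochastic multi-objective evolutionary optimizer with an epsilon-dominance
    post-analysis, protein-abundance design (PADMO) through a logarithmic
    flux-bound multiplier, identifiability analysis of flux scans via alternating
    conditional expectations (ACE) and mean-optimal-transformation (MOTA)
    grouping with a disease-stage classifier, and Morris elementary-effects,
    one-at-a-time robustness and first-order Sobol sensitivity screening.
    Models are read from SBML or a flat tabular reaction list; a seeded toy
    mitochondrion generator provides a self-contained test system.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    xml2,
    optparse,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    boot,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
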
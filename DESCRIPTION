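Package: bmpcomb
Title: Combinatorial Analysis of BMP Ligand Interactions Across Receptor Contexts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying pairwise interactions between Bone
    Morphogenetic Protein (BMP) ligands from combinatorial reporter screens.
    Implements the Interaction Coefficient, a piecewise-linear synergy and
    antagonism scale referenced to a ligand's interaction with itself;
    replicate-noise gating and per-pair interaction summaries; hierarchical
    clustering of ligands into context-dependent equivalence groups with a
    monochromaticity rule; dose-response (Hill) fitting and Relative Ligand
    Strength; a competitive ligand-receptor trimeric-complex equilibrium model
    with multi-start constrained least-squares parameter inference; and a
    synthetic screen generator that emulates the pairwise-titration experiment
    design so the whole pipeline can be exercised and validated without
    external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    deSolve,
    minpack.lm,
    pracma,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    Biostrings,
    jsonlite
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
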
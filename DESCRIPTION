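Package: ppdock
Title: Knowledge-Based Distance-Dependent Pair Potentials for
    Protein-Protein Docking and Evaluation
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives distance-dependent, knowledge-based atom-pair
    potentials from collections of protein-protein complexes and applies
    them as a scoring and objective function for rigid-body
    protein-protein docking. Provides Sybyl-style atom typing of PDB
    structures, potential derivation with a pooled reference state and a
    short-range Gaussian repulsion term, direct and precomputed-grid
    scoring, exhaustive rigid-body search over a deterministic SO(3)
    covering with optional knowledge-driven restriction of the
    translational search, greedy RMSD clustering and ranking of
    solutions and decoy ensembles, CAPRI-style quality assessment
    (f_nat, f_not, i_rmsd, l_rmsd), funnel analysis, Shrake-Rupley
    solvent-accessible surface areas and the relative-SASA predictor of
    docking success. A synthetic-fixtures module generates toy
    complexes, decoy ensembles and mini knowledge bases so the whole
    pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
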
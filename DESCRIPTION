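Package: helixkin
Title: Helix-Coil Folding Kinetics of Blocked Alanine Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of helix folding in blocked polyalanine peptides from
    conformational trajectories. Builds peptide conformations from backbone
    dihedrals, computes helicity metrics (i to i+4 backbone hydrogen bonds,
    dihedral-based helical residue counts, CA RMSD, radius of gyration),
    relaxation timescales from autocorrelation functions with biexponential
    fits, and two-state folding thermodynamics and kinetics. Coarse-grained
    kinetic models are obtained by RMSD leader clustering, core-based
    trajectory discretization, rate-matrix estimation, PCCA+ metastable
    lumping and optimal dimensionality reduction of the microstate rate
    matrix; folding pathways are characterized by committor probabilities,
    hydrogen-bond heat maps and neighbor-bond correlations. A cooperative
    Zimm-Bragg helix-coil simulator with exact transfer-matrix oracles
    provides ground-truth synthetic trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    bio3d,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
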
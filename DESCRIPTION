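Package: cdrentropy
Title: Conformational Entropy Analysis of Antibody Loop Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify the conformational heterogeneity of protein
    loop ensembles, in particular the complementarity-determining regions
    (CDRs) of single-domain antibodies, from biased molecular dynamics
    output. Provides parallel-bias metadynamics reweighting of frames into
    Boltzmann weights, GROMOS (Daura) and average-linkage clustering of
    conformations on pairwise C-alpha RMSD matrices, cluster-population and
    Ramachandran (phi/psi histogram) information entropies with weighted
    bootstrap uncertainty, residue contact maps and contact-based
    free-energy surfaces, split-half convergence diagnostics, and a
    synthetic multi-basin ensemble generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
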
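Package: pepdock
Title: Ab Initio Fold-and-Dock Monte Carlo Modelling of Peptide-Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simultaneous de-novo folding and docking of a flexible peptide
    onto a rigid receptor at a given binding site. Implements a two-stage
    Monte-Carlo protocol: a coarse-grained fold-and-dock stage that
    alternates rigid-body and backbone (small/shear/fragment-insertion)
    moves under simulated annealing with a Metropolis criterion, followed
    by Monte-Carlo-with-minimization refinement under van-der-Waals weight
    ramping. Includes a secondary-structure-aware backbone fragment picker,
    a coarse-grained centroid energy with total/interface/peptide
    partitions, greedy RMSD clustering with energy-based cluster ranking,
    interface backbone RMSD success metrics, and a fully synthetic toy
    benchmark (groove receptor with a planted native peptide) so the whole
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
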
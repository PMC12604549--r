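Package: retic
Title: Reticulate Phylogenies: Introgression Analysis on Species Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Network-based analysis of historical introgression from gene
    trees and SNP matrices. Provides a multispecies-coalescent simulator on
    level-1 phylogenetic networks with hybrid-edge inheritance probabilities,
    gene-tree quality control and branch-length normalization, exact topology
    weighting for four taxon groups with a chi-square test of the
    incomplete-lineage-sorting null, Patterson's D, f4-ratio and f-branch
    site-pattern statistics with block-jackknife errors and FDR control,
    pseudolikelihood scoring and majority-rule selection of candidate
    networks, calibration of networks to ultrametric node ages from gene-tree
    pairwise distances with an optimized power transform, and equal-rates
    discrete-trait ancestral state reconstruction on networks via displayed
    trees.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    ape,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
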
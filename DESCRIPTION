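Package: ptmx
Title: Analysis and Prediction of In Situ O-GlcNAc/Phosphorylation Cross-Talk Sites
Version: 0.1.0
Authors@R: person("ptmx", "developers", role = c("aut", "cre"),
    email = "ptmx@example.org")
Description: Toolkit for studying serine/threonine residues that can carry
    both O-GlcNAcylation and phosphorylation (in situ cross-talk).
    Provides residue conservation scoring on ortholog multiple sequence
    alignments (RCR and its flanking-region percentile rRCR), native
    two-tailed Fisher GO enrichment with Bonferroni correction, motif-x
    style overrepresented motif extraction with a conservation filter,
    mRMR (minimal-redundancy maximal-relevance) ranking of binary GO
    features, and cross-validated RBF-kernel SVM classifiers over sparse
    one-hot sequence windows plus selected GO indicator features, with
    specificity-stringency performance reporting. A seeded synthetic-data
    generator with known ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
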
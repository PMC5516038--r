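Package: brainRegulome
Title: Transcription Factor Contributions and Conserved RNA Structure
    Motifs in Regional Brain Expression
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Associates transcription factors (TFs) and conserved RNA
    secondary structures with regional gene expression in the brain.
    Candidate TF-gene interactions are derived from scored binding-site
    clusters near transcription start sites, per-gene sparse (LASSO)
    regression models of expression are calibrated against random models
    and filtered for multi-seed robustness, and coefficient-derived TF
    contributions are summarized per brain region with Shannon-entropy
    localization calls.  A second arm tests UTR regulatory elements of
    differentially expressed genes (fold-change-threshold moderated
    tests) for enrichment and characterizes overlapping conserved RNA
    structure motifs via base-pair fingerprints, phylogenetic subtree
    conservation, Fitch parsimony, recurrence and overlap clustering.
    A synthetic-data generator reproduces the statistical structure of
    all inputs so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
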
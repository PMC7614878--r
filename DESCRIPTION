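Package: haemscore
Title: Gene-Signature Scoring, Reference Projection and Survival
    Stratification for Hematopoietic Single-Cell Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies stem-cell aging and p53 pathway activation in
    hematopoietic stem and progenitor cell (HSPC) transcriptomes.
    Implements control-referenced gene-set scoring (aging signature,
    hematopoietic p53 score, cell-cycle phase assignment), spike-in
    calibrated highly variable gene selection, PCA reference-projection
    cell typing with two-tier k-nearest-neighbor label transfer,
    derivation of p53-dependent gene signatures from genotype-labeled
    cohorts, lineage-bias quantification, and score-stratified survival
    analysis (Kaplan-Meier, log-rank hazard ratios, multivariate Cox).
    Ships a negative-binomial single-cell cohort simulator with planted
    ground truth so every stage of the analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
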
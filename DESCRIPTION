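Package: scMatcher
Title: Cross-Technology Single-Cell Matching via Adversarial Latent Spaces
    and Minimum-Cost Maximum-Flow
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates two or more single-cell 'omics datasets with disjoint
    feature sets (e.g. scRNA-seq and CyTOF) into a shared, technology-invariant
    latent space using adversarially trained autoencoders, then pairs
    individual cells across technologies by solving a capacity-extended
    minimum-cost maximum-flow bipartite matching on the latent codes. Includes
    a k-nearest-neighbour divergence estimator for latent-space quality control
    and model selection, a negative-binomial branching-process simulator that
    provides ground-truth branch labels and pseudotime for benchmarking, and
    evaluation utilities (label accuracy, pseudotime and marker correlation,
    matched fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    jsonlite,
    Rcpp,
    RANN,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    clue,
    optparse,
    withr,
    yaml
biocViews: SingleCell, Transcriptomics, Proteomics, DimensionReduction
Config/testthat/edition: 3
RoxygenNote: 7.3.3
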
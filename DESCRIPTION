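Package: crossmod
Title: Cross-Species Concordance of Mouse Co-Expression Modules with
    Human Alzheimer's Disease Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for relating brain transcriptomes of genetically
    perturbed mouse strains to human late-onset Alzheimer's disease (AD)
    co-expression signatures. Covers expression-level preprocessing (TPM
    filtering, log transform, empirical-Bayes batch correction, PCA), a
    simplified negative-binomial Wald test for per-strain differential
    expression, weighted co-expression module discovery (soft-threshold
    selection, topological overlap, average-linkage clustering, eigengenes,
    module merging), module eigengene strain association (ANOVA with Tukey
    HSD), hypergeometric over-representation analysis, and the cross-species
    core: ortholog mapping, mouse-human module overlap scored by Jaccard
    index with a permutation null, and directional concordance between
    per-gene perturbation effects and human log2 fold changes. Includes a
    synthetic-data generator that emulates the multi-strain, multi-batch
    study design with known ground truth, so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    MASS,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    sva,
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
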
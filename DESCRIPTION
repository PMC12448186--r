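Package: parallelCline
Title: Cross-Species Parallel Latitudinal Transcriptome Differentiation
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting and quantifying parallel latitudinal gene
    expression differentiation across species from replicated bulk RNA-seq
    count data. Implements TPM normalisation and expression filtering, an
    empirical-Bayes moderated t-statistic differential expression engine with
    Benjamini-Hochberg adjustment, ortholog-restricted cross-species
    parallelism statistics (shared differential-expression enrichment,
    directionality concordance, log fold-change rank correlation), a
    calibrated tissue-bias classifier built on the tau tissue-specificity
    index, contingency-table enrichment of gene classes, and a per-gene
    four-population branch-length decomposition of expression divergence
    rooted by outgroup populations. A negative-binomial simulator with
    planted, cross-species-correlated latitudinal effects generates fully
    structured datasets with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: GeneExpression, DifferentialExpression, RNASeq, Transcriptomics
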
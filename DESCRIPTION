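Package: stageTau
Title: Stage-Specific Gene Expression in Time-Course Transcriptomics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for staging a two-group time-course transcriptome and
    extracting stage-specifically expressed genes. Single-sample gene set
    enrichment (ssGSEA) trajectories locate the peak of a pathway's activity
    and split the time course into progression and remission stages; the Tau
    specificity index (tau_max for stage-specifically high, tau_min for
    stage-specifically low expression) calls stage-specific genes at a
    configurable threshold; independent cohorts validate the calls with a
    Shapiro-Wilk-gated t/Wilcoxon test. Companion machinery covers sample
    heterogeneity (PCA on most-variable genes, between-group distance and
    correlation per time point), preranked GSEA with gene-set permutation,
    hypergeometric over-representation, signature-based immune scoring,
    non-negative least-squares cell-type deconvolution, and gene-by-cell-type
    Spearman correlation. A synthetic time-course generator with planted
    ground truth supports end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0), S4Vectors, SummarizedExperiment
Imports:
    methods,
    stats,
    utils,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    optparse,
    withr
biocViews: GeneExpression, TimeCourse, GeneSetEnrichment, Transcriptomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
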
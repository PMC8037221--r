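Package: icbBench
Title: Benchmarking Transcriptomic Biomarkers of Immune Checkpoint
    Blockade Response
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes 22 published transcriptomic biomarker scores (single
    checkpoint genes, signature means, weighted sums, IMPRES pairwise
    relations, ssGSEA and GSVA enrichment, principal-component and
    immunophenoscore schemes) and MCP-counter cell-population abundances
    from bulk log2(TPM+1) expression matrices; labels patients as
    responders or non-responders under four RECIST-derived strategies;
    and evaluates association (Wilcoxon, logistic regression),
    discrimination (ROC/AUC, sample-size-weighted prediction score,
    median-split sensitivity and specificity) and clinical efficacy
    (Kaplan-Meier, log-rank, objective response rate with Fisher's exact
    test) across multi-dataset immune checkpoint blockade cohorts.
    Includes a seeded synthetic-cohort generator with planted signature
    effects and analytic AUC expectations for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Matrix,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    pROC,
    optparse
biocViews: Transcriptomics, ImmunoOncology, Classification, Survival
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'evaluation.R'
    'survival.R'
    'labels.R'
    'enrichment.R'
    'signatures.R'
    'scoring.R'
    'benchmark.R'
    'cohort-io.R'
    'synthetic.R'
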
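Package: xburden
Title: Extreme-Phenotype Rare-Variant Burden Screening on the X Chromosome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case-control discovery pipeline for X-linked susceptibility
    genes in a male extreme-phenotype design: boolean gene-level collapsing
    of rare annotated variants (population-frequency, consequence and CADD
    filters), PCA-based cohort outlier removal, class-weighted L1-penalized
    logistic regression with stratified 10-fold cross-validation and
    fold-aggregated performance metrics, exact-test validation of selected
    genes with carrier-fraction summaries, and relative-quantification
    (2^-delta-delta-Ct) analysis of qPCR validation experiments. Includes a
    reproducible synthetic-cohort generator (VCF, phenotype and Ct tables)
    with a planted susceptibility gene so the whole pipeline is testable
    without access to restricted sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
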
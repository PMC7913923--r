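Package: mirtbi
Title: Plasma miRNA Biomarker Discovery for Experimental Traumatic Brain Injury
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a plasma small-RNA-seq biomarker
    discovery workflow for the rat lateral fluid-percussion model of traumatic
    brain injury and a matched human cohort: hemolysis and assay quality
    control, counts-per-million normalization and prevalence filtering,
    simplified negative-binomial Wald differential expression with
    Benjamini-Hochberg FDR control, nested leave-one-out cross-validated
    logistic-regression feature selection with permutation-tested AUC, droplet
    digital PCR absolute quantification by Poisson inversion, ROC and optimal
    cutpoint diagnostics, and elevated-subpopulation flagging. A synthetic
    cohort generator reproduces the statistical structure of the study design
    so the full pipeline is testable without the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
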
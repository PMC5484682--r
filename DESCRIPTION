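Package: sarcoSig
Title: miRNA-Regulated Gene Signatures for Sarcoidosis Severity
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Discovery and validation of miRNA-regulated peripheral blood
    gene-expression signatures along an ordinal disease-severity axis
    (healthy control, uncomplicated sarcoidosis, complicated sarcoidosis).
    Implements the severity-ordered Spearman screen with Benjamini-Hochberg
    adjustment, mirSVR-filtered miRNA-mRNA pair integration with
    anti-correlation testing, the sign-weighted standardized-expression
    severity score, ROC/AUC, trend and PCA evaluation, and empirical
    random-signature resampling tests of signature performance, together
    with a synthetic-cohort generator that emulates the assumed data
    structure for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: GeneExpression, Transcriptomics, Classification, miRNA
RoxygenNote: 7.3.3
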
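Package: geneRanker
Title: Gene Selection Methods for Two-Class Expression Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Feature ranking for two-class (case/control) gene-expression
    matrices. Implements three parametric scores (signal-to-noise ratio,
    Welch unpaired t, Fisher/LSD criterion), three nonparametric scores
    (threshold number of misclassifications, modal-ranking swap distance,
    z-weighted overlap punishment), random-forest-style root-gene voting
    (RFGS), and support-vector sample filtering (SVST), together with a
    repeated random k-fold linear-SVM benchmark, GenePattern GCT/RES/CLS
    file support, and a synthetic-data generator with planted
    differentially expressed genes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
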
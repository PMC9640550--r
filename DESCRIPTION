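Package: folategxe
Title: Set-Based Gene-Environment Interaction Scans with Genetically
    Predicted Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pooled case-control analysis workflow for detecting
    interactions between dietary folate intake and genetically predicted
    gene expression. Harmonizes folate exposure to dietary folate
    equivalents with sex-by-study control-based quartiles, computes
    PrediXcan-style predicted expression from variant weight sets, and
    tests each gene with a two-component mixed-effects score test: a
    1-df fixed component for the predicted-expression-by-exposure
    interaction and a variance-component term for residual variant-level
    interactions, combined over a weight grid by a Cauchy combination.
    Includes genome-scan multiple-testing control, quantile-stratified
    odds-ratio and variant-driver follow-up models, and a synthetic
    cohort generator with known ground truth for calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mvtnorm,
    vcfR,
    data.table
Config/testthat/edition: 3
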
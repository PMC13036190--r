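Package: epideg
Title: Multi-Contrast DEG Classification and Co-Regulation Analysis for
    Two-Tumor-Suppressor Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether two tumor suppressors regulate gene
    expression in a linear pathway, from multi-contrast differential-expression
    data. Classifies genes into single-mutant-specific and shared classes from
    three mutant-versus-wild-type contrasts, quantifies co- and inverse
    regulation of shared genes on the log2 fold-change scale, performs
    hypergeometric over-representation analysis with direction merging,
    redundancy collapse and silhouette-selected term clustering, and compares
    mutation-stratified tumor expression cohorts (PCA-reduced correlation,
    stage-stratified marker detection, heatmap scaling). A synthetic-data
    generator with planted class structure provides ground truth for recovery
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    cluster,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
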
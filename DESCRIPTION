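Package: dcx
Title: Differential Co-Expression Analysis of Two-Condition Microarray Studies
Version: 0.1.0
Authors@R: person("Airway", "Transcriptomics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested, reusable pipeline for two-group airway-epithelium
    microarray studies: synthetic data generation with planted ground truth,
    MSER-based array-scan gridding and spot quantification, background
    correction, quantile normalization and coefficient-of-variation
    filtering, covariate-adjusted gene-wise differential expression with
    Benjamini-Hochberg adjustment and an expected-false-positive sample-size
    calculator, resampling-based differential co-expression group detection,
    network betweenness-centrality topological attack and local
    over-representation analysis, plus the supporting clinical statistics
    (normality-gated group comparisons, logistic-regression optimal cut-off,
    harmonic-mean summarization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
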
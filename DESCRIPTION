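Package: mogat
Title: Multi-Omics Graph Attention Networks for Cancer Stage Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Classifies patient samples into cancer stages by integrating
    several omics views (mRNA expression, miRNA expression, DNA methylation).
    Each view is reduced by fully connected layers and passed through a
    multi-head graph attention network over a cosine-similarity patient graph;
    the per-view class distributions are fused through a cross-omics product
    tensor and a small fully connected head, and all branches are trained
    jointly. Includes correlation-based feature selection with per-view caps,
    a seeded synthetic multi-omics generator with planted class signal for
    validation, stage-pair binarization, and masking-based biomarker ranking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
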
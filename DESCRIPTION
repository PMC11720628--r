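Package: claimscope
Title: Explainable Unsupervised Anomaly Detection for Healthcare Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for finding care providers with atypical
    resource use in per-action healthcare billing data. Categorical features
    with high cardinality are embedded by latent semantic analysis (truncated
    singular value decomposition of a binary category-by-action co-occurrence
    matrix, rows l2-normalised); each provider's actions are collapsed into a
    single standardized profile vector (six summary statistics per numerical
    feature, mean embedding per categorical feature); a battery of unsupervised
    outlier detectors scores the profiles; providers are ranked by top-k
    consensus across detectors; and flagged profiles are explained with
    group-additive Shapley attributions and population-comparison reports. A
    synthetic claims generator with planted anomaly archetypes makes every
    stage testable without access to restricted insurer data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
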
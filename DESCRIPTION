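Package: corticompare
Title: Head-to-Head Comparison of Surface-Based Cortical Thickness Pipelines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for vertex-wise and region-wise comparison of cortical
    thickness measurements produced by two surface reconstruction pipelines
    observing the same cortex at different mesh resolutions. Builds a hybrid
    surface template by gradient-vector-flow driven free-form (B-spline)
    registration of one pipeline's average surface onto the other's, pairs
    the two thickness arrays by closest-point correspondence, and runs the
    full downstream statistical cascade: paired and two-sample t-maps with
    false-discovery-rate control, disease-effect difference maps, region
    tables with Tukey-Kramer post-hocs, Hedges g effect sizes with
    cross-pipeline z comparison, dependent-correlation (Steiger) tests, and
    forward-selected logistic ROC analysis with Hanley-McNeil correlated-AUC
    comparison. Includes a seed-deterministic synthetic cohort generator that
    emulates a two-pipeline longitudinal ageing/dementia study design for
    validation and calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
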
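Package: vatmets
Title: Visceral Fat Quantification from DXA Scans and Metabolic Syndrome
    Risk-Factor Cluster Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating abdominal visceral fat mass from
    dual-energy X-ray absorptiometry (DXA) scans via subcutaneous
    fat-layer boundary detection, anthropometry-based visceral fat
    prediction equations, International Diabetes Federation (IDF)
    metabolic-syndrome risk-factor flagging, and diagnostic evaluation of
    single and paired cut-points (ROC and precision-recall curves, Youden
    and maximum sensitivity-specificity-product cut-points, joint
    two-threshold accuracy grids). Includes a synthetic-data module that
    generates DXA abdominal phantoms with analytically known fat layout
    and correlated cohorts with realistic sex-stratified marginals, so
    the full pipeline is testable without participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
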
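Package: fedaki
Title: Simulated Federated Learning for ICU Acute Kidney Injury Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for studying 24-hour-lead-time
    prediction of acute kidney injury (AKI) in intensive-care patients across
    multiple hospitals. Provides a multi-site synthetic ICU data generator
    with known ground-truth risk structure, KDIGO 2012 temporal labeling of
    AKI onset and stage from creatinine, urine-output and dialysis streams,
    cohort exclusion rules with auditable attrition tallies, 6-hour feature
    windows with a 24-hour lead time, mean imputation, four classifier
    families with LASSO-based parsimonious feature selection and Platt
    calibration, calibration and decision-curve evaluation, and a simulated
    federated-averaging (FedAvg) study across heterogeneous sites with a
    hand-implemented neural network so that aggregation is bit-controllable.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    glmnet,
    xgboost,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
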
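Package: vitalrisk
Title: Dynamic Mortality Risk Prediction from Vital-Sign Streams During
    Paediatric Critical Care Transport
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for dynamic 30-day mortality risk
    prediction of critically ill children during inter-hospital transport
    to paediatric intensive care. Converts continuous vital-sign streams
    (heart rate, blood pressures, respiratory rate, SpO2, temperature)
    into age-standardised Z-scores, extracts class-balanced 10-minute
    window samples with thirteen per-channel statistics joined to static
    electronic health record variables, trains sample-level classifiers
    with patient-grouped cross-validation, fuses window probabilities
    into patient-level risk, evaluates against a PIM3-style baseline with
    patient-level bootstrap confidence intervals, and explains each
    window's prediction with model-agnostic Shapley attributions,
    including detection of survival-to-non-survival transition moments.
    A synthetic cohort generator with outcome-conditioned physiological
    deterioration makes every stage testable without restricted hospital
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    ranger,
    stats,
    utils,
    xgboost,
    yaml,
    zoo
LinkingTo: Rcpp
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
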
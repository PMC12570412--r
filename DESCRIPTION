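Package: polysocial
Title: Polysocial Risk Scores for Binary Health Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Construction and validation of polysocial risk scores: ranking of
    social determinants by gradient-boosted-tree information gain, forward
    model-size selection gated by sequential DeLong tests on cross-validated
    AUC, survey-weighted logistic modelling, integer point scores derived from
    regression coefficients, quintile-based risk categories, and full
    discrimination, calibration and reclassification diagnostics (C-statistic
    and its paired comparison, Hosmer-Lemeshow test, calibration bins, net
    reclassification improvement). Includes a synthetic cohort generator that
    emulates an age-oversampled survey design with sampling weights, so the
    whole pipeline can be exercised and tested without restricted data, and a
    chained-equations multiple-imputation sensitivity analysis for the
    variable-selection step.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    nnet,
    sandwich,
    xgboost,
    yaml
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
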
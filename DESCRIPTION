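Package: mdscalc
Title: Medical Device Score Calculator for Gross Motor Function in Cerebral Palsy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the Gross Motor Function Measure (GMFM-66) score of
    children and adolescents with cerebral palsy from the assistive medical
    devices they use, their age and their CP subtype ("Medical Device Score",
    MDS). Provides a calibrated synthetic cohort simulator, a four-family
    machine-learning harness (random forest, support vector machine,
    feed-forward neural net, gradient boosting), agreement statistics (Lin's
    concordance correlation coefficient, MAE, RMSE with bootstrap confidence
    intervals), GMFCS-stratified floor/ceiling diagnostics, and a
    resampling-based empirical power procedure for planning group-comparison
    sample sizes when the MDS stands in for the measured GMFM-66.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    randomForest,
    e1071,
    nnet,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
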
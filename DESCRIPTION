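Package: fcprognosis
Title: Prognostic Modeling of Clinical Outcomes from Functional Coupling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Cross-validated prediction of longitudinal clinical-outcome
    change from interregional functional-coupling (FC) matrices. Implements
    connectome-based predictive modeling (univariate edge selection, summed
    summary scores, one-variable linear model), correlation-kernel ridge
    regression with nested cross-validation for the l2 hyperparameter, and a
    meta-matching-style transfer stage that stacks proxy-phenotype
    predictors trained on large source cohorts. Model performance is scored
    as the mean correlation between predicted and observed outcomes over
    repeated random 4-fold splits, with significance from seeded permutation
    nulls and familywise-error control via the Westfall-Young max-statistic
    method. Includes a synthetic longitudinal cohort generator with planted
    edge-level effects, attrition, and bounded clinical scales so that every
    stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
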
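Package: paoptim
Title: Individualized Physical-Activity Pattern Recommendation via
    Counterfactual Survival Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assigning adults with high blood pressure an
    individually optimal accelerometer-derived physical-activity pattern by
    counterfactual survival prediction. Implements minute-level activity
    classification and weekly pattern labelling (weekend warrior, regular,
    light-activity, baseline), LASSO-Cox covariate selection, a Cox model
    with pattern-by-covariate interactions used as the single base learner
    of an S-learner, conditional inference trees characterizing the
    heterogeneity of the predicted optimal pattern, inverse probability of
    censoring weighted Brier score and time-dependent AUC, and Cox models
    for the mortality association of following versus not following the
    predicted optimal pattern. A synthetic-cohort generator with known
    data-generating truth supports validation of every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
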
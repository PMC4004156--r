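Package: photocrowd
Title: Consensus, Adaptive Workflow and Crowd-Size Calibration for
    Crowdsourced Photo Annotation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for running and calibrating crowdsourced annotation of
    field photographs, as used in point-of-sale tobacco-advertising
    surveillance. Provides plurality/supermajority consensus aggregation
    over independent raters, vote-fraction scores for ROC analysis,
    intersection-over-union clustering of near-duplicate crop boxes, a
    tiered adaptive tasking workflow with filtering, escalation,
    reverse-crop masking and graded payments, a jackknife crowd-size
    resampling procedure that estimates AUC against a gold standard at
    each crowd size, and a synthetic-study generator with heterogeneous
    rater sensitivity/specificity so the whole pipeline runs without any
    crowdsourcing platform or real images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
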
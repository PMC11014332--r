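Package: vidobs
Title: Direct-Observation Video Annotation, Fold Assignment and Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for turning event-based direct-observation annotation
    logs of human physical behavior into per-frame machine-learning datasets
    and evaluating per-frame classifiers. Rasterizes labeled intervals to
    second-by-second records under a majority rule with transition flagging,
    consolidates raw posture and intensity codes into sedentary, activity-type
    and intensity taxonomies, assigns whole videos to training/testing/
    evaluation folds by minimizing a weighted chi-square distance between fold
    and pooled class distributions (preventing frame-level leakage across
    folds), prepares frames (midpoint sampling, letterbox resize, training
    augmentations), trains a gradient-boosted-tree classifier on pose-keypoint
    features with test-fold early stopping, and reports confusion matrices,
    support-weighted precision/recall/F1, accuracy and one-vs-rest ROC AUC
    with per-class substitution and weight suppression. A seeded semi-Markov
    simulator generates synthetic multi-video sessions so the whole pipeline
    is testable without video data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
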
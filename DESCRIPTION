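Package: safefall
Title: Kinematic Analysis and Quality Scoring of Safe-Fall Motor Strategies from 2D Pose Sequences
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the biomechanical quality of falls from tracked
    2D human pose sequences (17 COCO-convention keypoints per frame). Reads and
    writes a documented pose-JSON dialect, repairs occlusion gaps, computes
    per-frame kinematic signals (vertical velocity, trunk inclination, bounding
    box aspect ratio, neck protection distance), segments fall phases around the
    peak hip deceleration, aggregates a 15-metric kinematic descriptor vector,
    and derives a hybrid composite safety score from effect-size feature
    selection and impurity-based weighting. Includes pre/post cohort statistics
    (Shapiro-Wilk gate, Mann-Whitney U, Benjamini-Hochberg correction, effect
    sizes), PCA + k-means motor-profile clustering, subject-independent grouped
    cross-validation for fall-quality classification, and a synthetic fall
    simulator producing pose-estimator-like output for three motor profiles
    (controlled tuck-and-roll, high-intensity chaotic, passive/freezing).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    randomForest,
    e1071,
    nnet,
    glmnet,
    xgboost,
    pROC,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
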
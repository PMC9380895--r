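Package: gaitfive
Title: Big Five Personality Assessment from Gait Keypoint Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Assessment of Big Five personality traits from 2-D body-keypoint
    gait sequences. Reads OpenPose BODY_25 output, normalises sequences to
    fixed 75-frame windows, translates coordinates to a MidHip origin and
    smooths them, constructs static and dynamic time-frequency gait features
    (coordinates, interframe differences, joint distances, joint angles, and
    5-level Haar wavelet bands; 2472 features in all), and fits per-trait
    regression models (linear, Gaussian process, random forest, support
    vector) behind a standardisation - PCA - sequential forward selection
    pipeline with repeated cross-validation. Models are evaluated with a
    psychometric framework: criterion validity, odd-even split-half
    reliability, and a multitrait-multimethod matrix for convergent and
    discriminant validity, plus a mapping of selected features back to body
    keypoints. A synthetic gait cohort generator with trait-driven kinematics
    makes the whole pipeline testable without access to recorded videos.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    kernlab,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
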
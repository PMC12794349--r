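Package: amide2d
Title: Synthetic Amide I 2D-IR Spectral Libraries and Machine-Learning
    Secondary-Structure Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates seeded synthetic two-dimensional infrared (2D-IR)
    amide I spectral libraries from protein secondary-structure
    specifications, formats them into feature frames (full-spectrum
    vectorisation and diagonal slices), and runs nested group
    cross-validation machine-learning analyses: ANOVA-F feature selection
    with support-vector classification of structural class, a chained
    support-vector regression of beta-sheet and alpha-helix content,
    AdaBoost helix-length classification, and sheet-registry regression.
    Includes the assessment metrics (accuracy, Cohen's kappa,
    precision/recall/F1, RMSE, pooled standard deviation) and end-to-end
    study orchestration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    e1071,
    class,
    rpart,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
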
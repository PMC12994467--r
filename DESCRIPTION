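Package: pronecg
Title: Conversion of Prone-Position 12-Lead Electrocardiograms to Standard Supine Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing standard supine 12-lead electrocardiograms
    (ECGs) from recordings taken in the prone position, where mirrored back
    electrodes distort the precordial leads. Implements three conversion
    routes: direct regression between inversely related lead pairs, an
    ECG-to-vectorcardiogram-to-ECG route using Dower-type lead transforms,
    and segment-wise tree-ensemble regression (random forest and gradient
    boosted trees) with participant-level data splitting; plus a hybrid
    combiner that transfers amplitude from the vector route onto the
    tree-route morphology. Includes beat detection and delineation,
    QRS/P/T morphology nomenclature classification, a synthetic
    paired-posture cohort generator built on a dipole-loop model, and
    agreement/diagnostic evaluation (RMSE, Bland-Altman, sensitivity,
    specificity, AUC, F1 with bootstrap confidence intervals).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    signal,
    ranger,
    xgboost,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    randomForest,
    withr
Config/testthat/edition: 3
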
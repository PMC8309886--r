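Package: rehabrecog
Title: Recognition of Cyclic Lower-Limb Rehabilitation Exercises from Wearable IMU Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end modeling pipeline for recognizing six scheduled
    lower-limb rehabilitation exercises from a single wearable inertial
    sensor. Provides a synthetic motion generator that follows the exercise
    schedules, tilt-angle preprocessing (projected and included-angle
    conventions) with relative-angle segmentation, extraction of 63 time-
    and frequency-domain features per 11-second exercise cycle including
    Hilbert-Huang marginal-spectrum centroid features of the first three
    intrinsic mode functions, multiclass recognizers (one-versus-one
    polynomial-kernel support vector machines and a Sugeno-type ANFIS
    initialized by subtractive clustering), stratified k-fold
    cross-validation with confusion-matrix and one-versus-rest ROC/AUC
    evaluation, and a pattern bank with traceable-diagram output for
    tracking recognized motions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
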
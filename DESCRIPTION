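Package: vimshrv
Title: Cardiac Assessment of Visually Induced Motion Sickness
Version: 0.1.0
Authors@R:
    person("VIMS", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for assessing visually induced motion
    sickness (VIMS) from single-lead ECG: Butterworth band-pass
    preprocessing, Pan-Tompkins style R-peak detection, NN-interval
    filtering, time- and frequency-domain heart rate variability (HRV)
    features (SDNN, pNN50, ln VLF, ln HF, ln VLF/ln HF), nine-zone
    autonomic-balance classification, Simulator Sickness Questionnaire
    (SSQ) scoring, baseline-adjusted ANCOVA with partial eta-squared and
    partial correlations, and permutation-validated binary motion-sickness
    classifiers (LDA, KNN, decision tree, linear SVM) under stratified
    10-fold cross-validation. Includes a synthetic-data module that
    emulates a 2D-versus-VR within-subject viewing experiment with known
    ground truth, and a sliding-window monitor for streaming decisions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
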
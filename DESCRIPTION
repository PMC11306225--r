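Package: pulsecheck
Title: Feasibility and Audit Tools for Wearable Waveform Prediction Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to test whether a wearable waveform such as the
    photoplethysmogram (PPG) carries enough well-conditioned information to
    predict a physiological target (systolic blood pressure, heart rate,
    reflected-wave arrival time). Implements a multi-valued-mapping checker
    that finds window pairs close in input space but far in label space, a
    k-nearest-neighbour (Kraskov-type) mutual-information estimator with the
    Info-Fraction ratio, handcrafted pulse-wave feature extractors, an MLP
    autoencoder featurizer, signal-quality and label-range filtering sweeps,
    train/test split leakage audits, and calibration-drift evaluation with
    AAMI/BHS grading. A seeded synthetic PPG/ABP/ECG cohort generator with
    controllable ill-conditioning makes every analysis testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    glmnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
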
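Package: eznorm
Title: Normative Abnormality Mapping of Structural Connectivity and
    Interictal iEEG for Epileptogenic-Tissue Localisation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to localise epileptogenic tissue from two routinely
    acquired modalities: fractional-anisotropy-weighted structural
    connectomes and interictal intracranial EEG. Patient measurements are
    z-scored against normative references (ComBat site harmonisation,
    robust age/sex correction, per-connection and per-band normative
    maps), summarised as regional abnormality profiles, and related to
    surgical resections through the distinguishability statistic D_RS
    (normalised Mann-Whitney U), linear-SVM separability of resected
    versus spared abnormalities, odds ratios, ROC AUC, a constrained
    depth-two decision tree and leave-one-out cross-validation. A
    synthetic-cohort generator with planted epileptogenic effects makes
    the full pipeline testable end-to-end without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    sva,
    e1071,
    signal,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
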
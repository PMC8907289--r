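Package: duopath
Title: Asymmetric Dual-Path 3D Convolutional Networks for Multimodal MR Tumor Grading
Version: 0.1.0
Authors@R: person("duopath", "maintainers", email = "duopath@example.org", role = c("aut", "cre"))
Description: Tools for binary meningioma grade classification from paired,
    co-registered T1 contrast-enhanced and T2-FLAIR MR volumes. Provides a
    synthetic two-channel tumor phantom generator with a controllable grade
    signal and a volume-ratio confound, NIfTI volume input/output and
    preprocessing (isotropic resampling, resampling to a reference grid,
    ROI cropping, intensity normalization, tumor volumetry and the
    R = V_T1CE / V_T2FLAIR statistic), an asymmetric dual-encoding-path 3D
    convolutional network with Glorot initialization trained by Adam on
    cross-entropy, leakage-free k-fold cross-validation with rotation
    augmentation, and evaluation utilities (confusion metrics with Grade II
    positive, ROC/AUC, per-fold ranges, location-stratified accuracy and
    misclassified volume-ratio summaries).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
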
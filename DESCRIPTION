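Package: escnn
Title: Ensemble Subgroup Convolutional Networks for EEG Sleep Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Automatic sleep-stage classification from single-channel EEG with
    an ensemble of subgroup-specialised sequential convolutional networks.
    Subjects are summarised by thirteen spectral band-power features, reduced
    by principal component analysis and partitioned into spectral subgroups by
    silhouette-selected k-means. One dual-scale convolutional network with
    cross-epoch (kernel-height-2) convolutions and squeeze-and-excitation
    feature recalibration is trained per subgroup on sliding windows of
    adjacent 30-second epochs; overlapping window predictions are normalised,
    consolidated and fused across subgroup models with inverse-squared
    cluster-distance weights. Includes EDF/EDF+ polysomnography input,
    preprocessing (notch, band-pass, z-normalisation), a seeded synthetic
    cohort generator with Markov hypnograms and stage-specific band
    signatures, leave-one-subject-out evaluation, and the standard staging
    metrics (accuracy, Cohen's kappa, per-class F1, sensitivity, specificity,
    one-vs-rest AUC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
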
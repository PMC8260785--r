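Package: saccramp
Title: Ramp-to-Threshold Analysis of Spontaneous Saccades and Hindbrain
    Calcium Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing spontaneously generated saccadic eye
    movements and simultaneously recorded single-cell calcium activity in
    larval zebrafish hindbrain. Provides velocity-threshold saccade
    detection and fixation segmentation from eye-position traces,
    saccade-triggered averaging with bootstrap confidence intervals,
    ANOVA-based screening of eye-movement responsive cells with
    Holm-Bonferroni correction, a PCA spherical-coordinate functional
    embedding with K-means cluster selection, selection and
    characterisation of pre-saccadic rise (SR) neurons, ROC-based choice
    probability for saccade-direction decoding, a ramp-to-threshold
    accumulator model that predicts saccade times from population
    activity, ideal-observer baselines, and resampled median-effect-size
    statistics for laser-ablation experiments. A synthetic-data module
    generates eye traces, calcium traces, image stacks and ablation
    records with known ground truth so the full pipeline can be exercised
    and validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    cluster,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
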
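Package: delaydecode
Title: Analysis of Memory-Guided Perceptual Decision Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for trial-based analysis of head-fixed
    delayed-response licking experiments: four-parameter psychometric
    fitting and session metrics, logistic choice models for optogenetic
    and chemogenetic perturbation effects (including nested-model
    likelihood-ratio tests and single-step multiple comparisons),
    rolling-percentile baseline correction and dF/F extraction for
    two-photon calcium imaging, ROC/AUC single-neuron selectivity with
    permutation nulls, cross-validated linear population decoding and its
    linkage to response time via linear mixed models, dual-channel fiber
    photometry motion correction and cell-type choice-coding comparisons,
    and detection of optogenetically evoked synaptic responses in slice
    recordings.  A synthetic-data generator with known ground truth
    emulates every input modality so all stages are testable without
    animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    e1071,
    lme4,
    lmerTest,
    sandwich,
    MASS,
    jsonlite,
    yaml,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    multcomp
Config/testthat/edition: 3
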
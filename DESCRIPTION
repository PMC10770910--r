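Package: mmnpipe
Title: Simulation and Analysis of the Duration Mismatch Negativity in
    Auditory Oddball EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for duration mismatch-negativity (MMN)
    studies using passive auditory oddball EEG at several stimulus onset
    asynchronies. Provides a synthetic oddball-EEG cohort generator
    (session schedules, tone stimuli, event-locked scalp potentials with
    1/f background activity, ocular and movement artifacts), the full
    preprocessing chain (decimation, Chebyshev band-pass filtering,
    bad-channel detection and spherical-spline interpolation, epoching,
    two-stage amplitude-based artifact rejection, baseline correction,
    mastoid-adjacent re-referencing, ocular denoising), per-subject MMN
    amplitude measurement at frontal electrodes, and the inference layer:
    linear mixed-effects models, planned paired comparisons, JZS Bayes
    factors, bootstrap Spearman correlations, and spatio-temporal
    cluster-based permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    jsonlite,
    lme4,
    lmerTest,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
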
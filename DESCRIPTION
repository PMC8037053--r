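Package: cogload
Title: EEG-Based Cognitive Load Assessment for Code Comprehension
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for assessing programmer cognitive load
    from multichannel scalp EEG recorded during code-comprehension tasks.
    Provides a protocol-structured synthetic cohort generator (band-limited
    noise EEG with load-dependent theta/alpha modulation, gaze streams,
    areas of interest, NASA-TLX scores), EEG preprocessing (zero-phase FIR
    filtering, bad-channel detection, spherical-spline interpolation,
    average re-referencing, extended-Infomax ICA with automated artifact
    component flagging), extraction of 3007 per-window spectral and
    time-domain features including task-engagement indexes, baseline
    normalization against fixation-cross intervals, task segmentation with
    second-order feature transformation, feature selection (Kruskal-Wallis,
    Mann-Whitney, ReliefF, normalized mutual information, PCA), classifier
    evaluation under nested leave-one-subject-out cross-validation, and
    space-time localization of high-load code regions by fusing EEG feature
    time-courses with density-clustered eye-tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    e1071,
    class,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
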
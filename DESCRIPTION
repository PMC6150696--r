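Package: stridelab
Title: Stride-Level Analysis of Hindlimb Locomotor EMG and Kinematics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for treadmill locomotion studies that
    record motion-capture markers and multi-channel intramuscular EMG. Raw
    marker trajectories are low-pass filtered, projected onto the sagittal
    plane, and the knee is reconstructed by two-circle triangulation from
    femur and tibia lengths to bypass skin-movement artifact; raw EMG is
    band-pass filtered, rectified and smoothed into envelopes; strides are
    segmented at tibialis anterior burst onsets, screened by duration,
    Tukey-fence EMG artifact and missing-kinematics rules, and time-normalized
    to 100 samples. Per-stride features (stance percentage, joint angles and
    ranges of motion, limb length and angle, baseline-normalized integrated
    extension-burst EMG) feed linear mixed-effects models with
    Bonferroni-corrected post-hoc contrasts and paired t-tests for muscle
    masses. A synthetic hindlimb-gait generator with known ground truth makes
    every stage verifiable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lme4,
    lmerTest,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
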
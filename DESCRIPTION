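Package: lfpdecode
Title: Decoding Hindlimb Kinematics from Intraspinal Local Field Potentials
Version: 0.1.0
Authors@R: person("lfpdecode", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for decoding bilateral hindlimb joint angles from multichannel
    intraspinal local field potential (LFP) recordings during treadmill locomotion.
    Implements band-limited envelope feature extraction (Butterworth notch,
    six-band filter bank, rectified-envelope and windowed-amplitude features,
    lagged 3D feature tensors), a three-dimensional convolutional neural network
    regressor with partial least squares and Lasso baselines under threefold
    cross-validation, gait-cycle-locked event-related
    desynchronization/synchronization maps, adaptive-partitioning mutual
    information analysis, walking-cadence band-power comparisons, and a
    synthetic-session generator with known ground-truth gait-phase coupling for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    tools,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
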
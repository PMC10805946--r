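Package: interpgaze
Title: Interpolated Gaze-Behavior Sensor Data via a Semi-Supervised InfoGAN
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how a continuous personality trait modulates
    wearable gaze-behavior sensor data (9-channel accelerometer, gyrometer and
    electrooculography streams at 50 Hz) while holding individual attributes
    fixed.  Implements a semi-supervised information-maximizing adversarial
    generator (ss-InfoGAN) over 9 x 512 sensor windows with continuous trait
    codes, categorical person-identity codes and a time code; the three
    disentanglement evaluations (real data, generated data, and real-and-
    generated data tests with leave-one-out cross-validation); and the
    movement-amplitude autocorrelation peak-lag analysis used to read out
    trait-modulated saccade-fixation periodicity from trait-interpolated
    generated data.  A ground-truthed saccade-fixation renewal simulator
    stands in for real recordings so that every claim is testable as
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
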
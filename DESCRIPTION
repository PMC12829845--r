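Package: rungait
Title: Wearable Running-Gait Analysis with IMU-UWB Fusion and a
    Diffusion-Transformer-LSTM Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for wearable running-gait monitoring. Simulates 9-axis
    MEMS inertial (accelerometer, gyroscope, magnetometer) and ultra-wideband
    (UWB) ranging streams from articulated 17-joint gait motion; models sensor
    scale-factor, zero-bias and Earth-rate errors with six-position
    calibration; performs SDS-TWR ranging, multilateration and NLOS outlier
    gating; fuses inertial dead reckoning with UWB positions through a Kalman
    filter and Rauch-Tung-Striebel smoother; computes joint angles,
    centre-of-mass trajectories and dynamic-time-warping gait-phase
    segmentation; and trains a compact diffusion-transformer/LSTM (DiT-LSTM)
    sequence classifier for multi-class running-posture recognition on
    windowed, z-scored sensor matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
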
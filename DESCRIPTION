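Package: kneeadl
Title: Activity-of-Daily-Living Recognition from Dual Embedded Knee IMU Streams
Version: 0.1.0
Authors@R: person("kneeadl", "maintainers", email = "maintainers@kneeadl.dev", role = c("aut", "cre"))
Description: Tools for recognising activities of daily living (walking,
    jogging, stair use, sit-to-stand transitions, knee bending, quiet
    standing) from two asynchronously streaming inertial measurement units
    mounted on the femoral and tibial sides of a knee joint. The package
    provides a rigid-body kinematic simulator of dual-device 50 Hz IMU
    streams for eight activity classes, time-bin synchronisation of the two
    streams onto a shared 100 ms grid, dual-path Butterworth filtering
    (low-pass accelerometer, high-pass gyroscope), short-time Fourier
    spectrogram tensors, a dual-branch recurrent/convolutional classifier
    trained with Adam, and an evaluation harness reporting per-class
    precision, recall and F1 with confusion matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
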
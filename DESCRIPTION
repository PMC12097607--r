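Package: jointkin
Title: Joint Kinematics and Range of Motion from Wearable Inertial Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Toolkit for postoperative joint-motion assessment from body-worn
    inertial measurement units (IMUs). Provides ZYX Euler-angle and rotation
    kinematics, per-sensor attitude estimation with complementary filtering and
    stillness detection, a linear Kalman filter fusing inertial dead reckoning
    with position/velocity fixes, wavelet universal-threshold denoising of
    motion signals, kinematic-constraint self-calibration of two limb-mounted
    sensors to a hinge joint (joint axis and joint-center lever arms), joint
    angle and range-of-motion estimation, an error-injection experiment
    harness, and a ground-truthed rigid-body hinge-limb simulator used as the
    test fixture for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
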
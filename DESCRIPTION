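Package: myoknn
Title: Myoelectric KNN Velocity Decoding and Closed-Loop Posture Matching
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis stack for multichannel electromyographic
    (EMG) velocity control of a three degree-of-freedom virtual hand. Provides
    a synthetic EMG generator with directionally tuned muscles, crosstalk
    mixing and calibrated signal-to-noise ratio; sliding-window mean absolute
    value and waveform length feature extraction; assumed-intent training
    label construction from a cued posture protocol; an inverse-distance
    weighted K-nearest-neighbor velocity decoder with leave-one-out variance
    accounted for; a closed-loop posture-matching task engine with success,
    trial-time and path-efficiency metrics; EMG signal-quality estimation
    (crosstalk correlation, burst SNR, duty cycle, Box's M); and the
    session-level regression and nonparametric analyses used to assess
    controller stability over time and across arm postures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
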
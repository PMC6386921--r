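Package: hierfusar
Title: Hierarchical Deep Fusion for Egocentric Activity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-layer hierarchical recognition of activities of daily
    living from a wearable hybrid sensor system combining an inertial
    measurement unit (IMU) and an egocentric camera. A recurrent
    motion-state classifier routes each 3 s sensor window to a coarse
    motion-state group (lying, sedentary, standing, walking, ...), and a
    group-restricted image classifier (single frame or frame sequence)
    resolves the specific activity within the group. Includes the
    many-to-many activity/motion-state correspondence algebra with
    packaged groupings, frame-to-sensor time-window alignment, direct
    softmax fusion baselines, per-class F1 evaluation with a
    leave-one-sequence-out protocol, an online per-frame cost model, and
    a seeded synthetic multimodal data generator so the whole pipeline
    runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    nnet,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
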
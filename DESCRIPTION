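Package: occlutrack
Title: Gaze Analysis for Tracking Intermittently Occluded Targets on Circular Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing oculomotor behavior while tracking a target
    that moves on a circular trajectory and is intermittently occluded. The
    package covers the full processing chain: head-pose estimation from
    fiducial-marker detections with an unscented Kalman smoother, mapping of
    eye-camera gaze onto screen coordinates, denoising and piecewise-linear
    segmentation of the gaze signal with saccade versus pursuit/fixation
    classification, polar (phase/radius) decomposition of tracking error, and
    summary statistics for anticipatory saccades, pursuit gain, cumulative
    phase coverage, discrimination performance and the accumulation of
    prediction uncertainty during occlusion. A synthetic-data generator
    produces complete sessions (trial schedules, gaze traces, marker streams,
    responses) with configurable oculomotor parameters so the whole pipeline
    can be exercised and validated without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    yaml,
    Matrix,
    lme4,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
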
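Package: pupiltrack
Title: Simulation and Analysis of Pupil-Tracking Motion Correction for
    Anterior Segment OCT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for simulating and characterizing a video-oculography
    pupil tracker driving closed-loop lateral motion correction of an
    anterior segment optical coherence tomography (ASOCT) scanner.
    Includes a synthetic scene generator (dark-pupil/bright-iris camera
    frames, fixational eye-motion trajectories with 1/f-type spectra, and
    OCT M-scan volumes), a threshold/morphology/connected-component
    centroid tracker, a discrete-time proportional correction loop with
    calibrated gain and transport latency, bench-characterization
    pipelines (step-response frequency analysis, cross-correlation
    latency, summed-voxel-projection edge traces, motion-correction
    transfer functions, loop-gain optimization), an analytic
    latency-residual model, and B-scan registration and averaging
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
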
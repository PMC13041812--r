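Package: riskseq
Title: Risk-Ranked Behavioral Sequences and Fiber Photometry on the
    Elevated Plus Maze
Version: 0.1.0
Authors@R:
    person("riskseq", "maintainers", email = "riskseq@example.org",
           role = c("aut", "cre"))
Description: Rule-based segmentation of elevated-plus-maze exploration into
    risk-ranked behavioral sequences (closed-to-closed, NoGo, Go,
    closed-to-open), frame-wise kinematic and postural features from pose
    tracking, a risk-assessment index, dual-wavelength fiber-photometry
    preprocessing to z-scored dF/F (zero-phase Butterworth low-pass,
    RANSAC isosbestic motion correction, within-animal session z-scoring),
    peri-event alignment and time binning, and sequence-resolved inference
    via spline-by-sequence generalized estimating equations with AR(1)
    working correlation, robust sandwich covariance, and animal-level
    bootstrap confidence bands. A synthetic-data module generates pose
    tracks, behavioral annotations, and interleaved two-channel photometry
    with known ground truth so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
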
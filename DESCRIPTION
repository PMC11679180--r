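Package: limbstat
Title: Static Link-Segment Analysis of Sagittal Postures from 2D Pose
    Keypoints
Version: 1.0.0
Authors@R:
    person("Limbstat", "Developers", email = "limbstat@example.org",
           role = c("aut", "cre"))
Description: Tools for static inverse-load analysis of human lower-limb
    postures in the sagittal plane. Reads 2D pose keypoints in the
    BODY_25 layout emitted by common markerless pose estimators,
    calibrates pixel coordinates into a metric world frame, builds a
    stature- and mass-scaled anthropometric model, locates segmental and
    whole-body centres of mass, distributes ground reaction forces
    between the feet under static equilibrium (double or single
    support), and recovers joint forces and moments at the ankle, knee
    and hip by a segment-by-segment free-body recursion. Ships a
    synthetic posture generator with analytically known ground-truth
    loads, an independent brute-force equilibrium oracle, and a
    command-line pipeline with structured JSON/CSV reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
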
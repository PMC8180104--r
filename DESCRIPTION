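Package: ratgait3d
Title: Three-Dimensional Gait and Allodynia Phenotyping for Rodent
    Neuropathic Pain Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies treadmill gait of rats after unilateral spinal nerve
    ligation (SNL) from three-dimensional joint-marker trajectories. Detects
    touchdown and lift-off events from toe kinematics (or imports manually
    entered event tables), segments gait cycles, and computes per-joint
    sagittal fluctuation (top-minus-bottom height), heel step and stride
    lengths in the treadmill belt frame, cumulative both-foot contact time,
    circular (swing) phase durations and their right/left ratio R, and the
    von Frey percent-decrease summary of mechanical allodynia. Includes a
    calibrated synthetic cohort generator for sham and SNL groups so that
    every stage of the pipeline is testable by parameter recovery, plus the
    group-comparison statistics (paired t and Mann-Whitney) used for
    sham-versus-SNL phenotyping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
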
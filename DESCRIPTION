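Package: stsbalance
Title: Static and Dynamic Balance Analysis of Sit-to-Stand Transfers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-body balance analysis of sit-to-stand (STS) movements from
    3D marker trajectories and force-plate recordings. Computes whole-body
    centre-of-mass kinematics, inertia and angular momentum; builds a
    functional base-of-support (BOS) polygon model of the shod foot; derives
    the four static balance metrics (COM ground-projection to BOS distance,
    COM-COP distance, COM speed, average angular speed) together with
    still-standing bounds; solves the 3D foot placement estimator (FPE) by
    projecting the equivalent single-body state onto the travel plane and
    root-finding the planar balance equation, yielding dynamic balance
    margins; segments STS repetitions automatically with k-means++ phase
    clustering plus adaptive thresholds; and compares age groups at seat-off
    with exact non-parametric tests. A synthetic-cohort generator with full
    ground truth (a planar three-link chain plus feet) exercises the whole
    pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
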
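Package: dvjagree
Title: Drop Vertical Jump Knee Kinematics and Two-Device Agreement Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for markerless motion analysis of the drop vertical jump
    (DVJ), a standard screening task for non-contact anterior cruciate
    ligament injury risk. Computes per-frame coronal (abduction/valgus) and
    sagittal (flexion) knee angles from skeletal joint trajectories using
    knee-to-hip and knee-to-ankle segment vectors, detects the initial
    contact, peak coronal and peak sagittal events with kinematic triggers,
    and quantifies agreement between two tracking devices with
    normality-gated paired location tests and the single-measure
    absolute-agreement intraclass correlation coefficient ICC(A,1) with
    F test and confidence interval. Includes power/sample-size calculators
    for paired t, Wilcoxon signed-rank and ICC designs, and a synthetic
    paired-device DVJ skeleton simulator with known ground truth for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
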
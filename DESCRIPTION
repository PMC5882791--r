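Package: strokesight
Title: Digital Visual Screening Battery for Stroke: Simulation and Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational core of a tablet-based visual screening battery for
    stroke survivors. Implements visual-angle screen geometry with
    Goldmann-III-equivalent stimulus sizing, an adaptive (2-down-1-up)
    tumbling-E near-acuity staircase with logMAR threshold estimation,
    reaction-time-corrected kinetic perimetry with field-map construction and
    three-way defect grading (hemianopia, quadrantanopia, macula sparing),
    line-bisection and cancellation scoring for visual inattention (laterality
    index), generative simulated observers for all three instruments, and
    diagnostic test-accuracy statistics over 3x3 intention-to-diagnose
    contingency tables (sensitivity, specificity, predictive values,
    Clopper-Pearson intervals, paired sample-size calculation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
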
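Package: vfdtrial
Title: Simulation and Outcome Scoring for Visual Field Defect Rehabilitation Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing, simulating, and analysing randomized trials of
    visual rehabilitation in post-stroke visual field defects. Implements the
    Humphrey 24-2 perimetry grid in eye-native and common binocular coordinates,
    binocular-integrated visual fields (pointwise best-eye sensitivity),
    defective-field classification from total-deviation probability maps, the
    improved-visual-area and mean-total-deviation outcome measures, a
    normality-gated statistical battery (Shapiro-Wilk, Mann-Whitney U, Wilcoxon
    signed-rank, t tests, Pearson chi-square, Fisher exact), a synthetic
    two-arm patient-cohort generator with test-retest noise, and a headless
    simulator of quadrant-based visual perceptual learning training sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
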
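Package: exerscore
Title: Pose-Comparison Scoring, Session Logic and Trial Statistics for a
    Monocular-Camera Exergame
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An engine for angle-based comparison of captured human poses
    against regulated reference postures, as used in camera-based exercise
    games ("exergames"). Provides a canonical 10-landmark skeleton data model
    with JSON-lines and CSV pose-stream I/O, joint-angle extraction with
    temporal smoothing, the piecewise recognition score S(D; Dst, Sst) built
    on the summed angular deviation D, a 10-minute aerobic/resistance session
    protocol with a points-and-rewards ledger, heart-rate target-zone
    computation (HRmax = 208 - 0.7 x age), a seeded synthetic skeleton-motion
    generator for six aerobic movements, and summary-statistics inference
    (one-way ANOVA with eta-squared and Cohen f, pooled t tests, rank tests,
    and noncentral-F power/sample-size calculation) for three-arm trials
    reported as mean (SD) tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
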
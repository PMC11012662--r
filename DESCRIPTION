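Package: trunkmetrics
Title: Trunk Asymmetry Quantification from Back-View Photograph Landmarks
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Computes quantitative trunk-asymmetry parameters for scoliosis
    assessment from nine manually tagged anatomical landmarks on a back-view
    clinical photograph: six signed angles (shoulder, axilla and waist height
    angles; left and right waistline angles and their difference) and four
    left/right hemitrunk area ratios (shoulder, waist, pelvic, total) obtained
    by dividing the trunk along the C7 plumbline. Includes the full
    observer-reliability toolbox used to validate such tools (two-way ANOVA
    intraclass correlation coefficients in all four single/average x
    consistency/agreement forms with F tests and 95% confidence intervals,
    standard error of measurement, inter- and intra-observer study runners,
    group comparison), a synthetic rater-study simulator with known variance
    components, and a command-line interface for batch measurement,
    reliability reports and simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nortest,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
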
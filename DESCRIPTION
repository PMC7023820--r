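Package: pspvt
Title: Simulation and Scoring for a Pedal Selective Psychomotor Vigilance Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A headless implementation of a pedal selective psychomotor
    vigilance task (PS-PVT): a stimulus-protocol engine with alternating
    parallel/cross response-mapping blocks, a plain-text trial-log format
    with readers, writers and validators, a scorer computing six pedal
    response indicators (mean response time, pedal error frequency,
    hesitation frequency and length, error correction time, cross-mode
    effect), a stochastic virtual-subject simulator with age-group presets
    calibrated to published young/older contrasts, and the accompanying
    statistics (Bland-Altman limits of repeatability, unbalanced two-way
    ANOVA with Type III sums of squares, Bonferroni pairwise comparisons).
License: MIT
Encoding: UTF-8
Imports:
    car,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
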
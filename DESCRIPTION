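Package: circafly
Title: Circadian Locomotor Activity and Expression Analysis for Drosophila
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Desk-scale analysis chain for Drosophila circadian behaviour and
    companion expression statistics. Reads Trikinetics-style activity monitor
    files, rebins beam-cross counts, maps clock time to Zeitgeber/Circadian
    time, flags in-recording death, and scores rhythmicity (chi-square
    periodogram plus autocorrelation), free-running period, morning index,
    morning/evening anticipation, evening activity onset, constant-darkness
    phase and sleep (5-minute inactivity rule). The expression arm provides
    probe filtering, quantile normalization, two-class SAM with permutation
    FDR, hypergeometric target-set enrichment, 2^-ddCt relative
    quantification, staining-intensity and dual-luciferase normalizations.
    A seeded synthetic-data generator produces activity cohorts, expression
    matrices and Ct tables with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
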
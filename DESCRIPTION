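Package: doubleread
Title: Inter-Reader Discordance Analysis for Double-Read RECIST 1.1 Trials
Version: 0.1.0
Authors@R:
    person("Median", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing inter-reader discordance in oncology
    clinical trials with blinded independent central review and double
    reads under RECIST 1.1. Derives per-visit overall responses from
    lesion-level reads, extracts the four standard kinds of discrepancy
    between paired reader timelines (progressive disease declared, date of
    progressive disease, best overall response, date of first response),
    estimates discrepancy rates over trial time and discrete discrepancy
    hazards over patient follow-up with exact binomial confidence
    intervals, screens baseline-derived risk factors by univariate odds
    ratios, and evaluates baseline-only discordance prediction with
    cross-validated classifiers. A synthetic double-read trial simulator
    with known ground truth supplies every upstream input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
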
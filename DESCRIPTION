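Package: mircircuit
Title: Design and Evaluation of miRNA-Input Cell-State Classifier Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for designing and evaluating synthetic gene circuits that
    classify cell states from endogenous miRNA profiles. Merges multi-source
    miRNA expression datasets by mature sequence, predicts circuit output per
    sample with a mechanistic steady-state bow-tie model of Hill-type miRNA
    repression and transcription-factor activation, searches for miRNA input
    sets maximizing a log10 classification margin (cMargin) with optional
    bootstrap pruning, runs single-parameter and combinatorial model screens,
    and quantifies flow-cytometry readouts (relative/absolute units,
    percentile gating, viability) and micropatterned-colony radial expression
    profiles. Includes seeded synthetic-data generators with ground-truth
    manifests so every analysis is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
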
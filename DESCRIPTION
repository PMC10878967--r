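Package: sweptrial
Title: Design and Analysis of Stepped-Wedge Cluster-Randomized Trials of
    Intrapartum Care
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for stepped-wedge cluster-randomized trials of labour and
    childbirth care: Robson ten-group classification of births with
    audit-and-feedback tables, modified-Poisson generalized estimating
    equations with exchangeable working correlation and the Mancl-DeRouen
    bias-corrected sandwich variance with t(N-2) inference, intraclass
    correlation estimation with cluster-bootstrap intervals, closed-form and
    simulation-based power for cross-sectional stepped wedges with unequal
    cluster sizes, and a calibrated individual-level synthetic-data
    generator so the full analysis pipeline can be run and tested without
    access to trial data.
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
    yaml
Config/testthat/edition: 3
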
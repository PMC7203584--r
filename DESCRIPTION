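Package: attractorchoice
Title: Attractor Dynamics and Choice Perseveration in Value-Based Decision Making
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses choice perseveration in a two-option
    value-based foraging task. Implements a one-dimensional double-well
    attractor model of the decision process with inter-trial carryover, an
    adaptive sequence-design generator built from individually estimated
    indifference points (logistic psychometric fits), synthetic participant
    cohorts for end-to-end pipeline validation, perseveration-index and
    choice-curve analyses, and a parallel constraint satisfaction (PCS)
    network as an alternative hierarchical choice mechanism.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
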
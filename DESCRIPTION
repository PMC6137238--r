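Package: arnet
Title: Egocentric Influence-Network Analysis for Allergic Rhinitis Management
Version: 0.1.0
Authors@R:
    person("Maintainer", "Packaged", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for egocentric social-network analysis of the influences on
    allergic rhinitis (AR) self-management decisions. Scores the single-question
    ARIA severity item and the mini Rhinoconjunctivitis Quality of Life
    Questionnaire (mini-RQLQ), canonicalises free-text alter labels into a
    versioned influence taxonomy, detects name-generation data saturation,
    aggregates concentric-circle placements into cohort networks, computes the
    weighted network-alter-density statistic with circle weights 4/3/2/1, writes
    and reads NetDraw-compatible VNA files, builds quality-of-life-stratified
    analysis reports, and generates calibrated synthetic cohorts for testing and
    parameter-recovery studies.
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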
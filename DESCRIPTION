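Package: ephystat
Title: Spike-Train Analysis for In Vivo Pharmaco-Electrophysiology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for extracellular single-unit recordings in
    pharmacological studies of monoaminergic systems. Implements interspike-
    interval (ISI) two-threshold burst detection, firing-rate and
    spontaneously-active-neurons-per-track population metrics,
    microiontophoresis recovery (RT50) and inhibition (IT50) indices,
    peristimulus time histogram (PSTH) construction with duration-of-
    suppression extraction, antagonist-disinhibition (tonic activation)
    percent-change analysis, per-rat aggregation with one- and two-way
    ANOVA comparison layers, and a point-process simulator (gamma-renewal,
    two-state bursting, inhomogeneous Poisson by thinning) that provides
    ground truth for every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
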
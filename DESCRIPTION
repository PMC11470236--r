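Package: mgrn
Title: Multi-View Gating Retrieval Networks for Medication Recommendation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Implements a multi-view gating retrieval network (MGRN) for
    medication recommendation from longitudinal electronic health records.
    Patient visits (sets of diagnosis and procedure codes) are embedded and
    matched against learned drug representations at three granularities --
    visit level, sequence level, and token level -- and a gating drug
    retrieval module scores each historically prescribed drug for reuse at
    the current visit.  Training minimises a joint objective combining
    binary cross-entropy, a multi-label hinge loss, and an adaptive
    drug-drug interaction penalty.  The package bundles a synthetic
    longitudinal-cohort simulator with a known diagnosis-to-drug rule and
    controllable drug persistence, evaluation protocols (multi-round
    testing, ablations, visit-index stratification, training-set deletion
    sweeps), and a command-line interface, so the full pipeline runs
    without access-restricted clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
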
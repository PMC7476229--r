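Package: infantERP
Title: Longitudinal Infant ERP Face-Categorization Pipeline
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end analysis pipeline for longitudinal infant
    event-related potential (ERP) studies of face categorization. Simulates
    two-visit cohorts of raw multi-channel EEG with known component-level
    ground truth (P1, N290, P400, Nc), performs zero-phase band-pass
    filtering, epoching, baseline correction, three-criterion artifact
    rejection and common-average referencing, scores component mean
    amplitudes, peak latencies and peak-to-trough amplitudes, classifies
    face-house difference scores into discrete states and summarises their
    between-visit transitions as descriptive Markov tables, and provides
    within-subject inferential statistics (2x2 repeated-measures ANOVA with
    partial eta squared, paired t-tests with Cohen's d, and the
    Brown-Forsythe variance-homogeneity test).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    signal,
    car,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
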
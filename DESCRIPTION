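Package: nacshell
Title: Photometry, Behavioral and Expression Analysis of Accumbens Shell Gradients
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-locked analysis of dual-channel fiber-photometry recordings
    (isosbestic motion correction, delta-F-over-F0 normalization, peri-stimulus
    averaging, epoch AUC and extrema), scoring of operant reward-consumption,
    optogenetic block and real-time place-preference sessions, marker
    co-expression quantification from sparse single-cell count matrices, and
    the matching inferential statistics (paired t-tests, mixed repeated-measures
    ANOVA, Sidak post-hoc comparisons). Ships simulators for every input class
    so the full pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    methods,
    pracma,
    signal,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
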
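Package: erpmicrostates
Title: EEG Microstate Analysis for Event-Related Potentials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Topographic microstate analysis of event-related potentials
    (ERPs): polarity-invariant modified k-means clustering of scalp maps,
    Krzanowski-Lai selection of the number of microstates, two-level
    (subject then group) template extraction, backfitting of global
    templates by absolute spatial correlation, and the standard microstate
    metrics (mean duration, occurrence per second, coverage) together with
    the within-subject ANOVA / Duncan post-hoc layer used to compare
    experimental conditions. Includes a synthetic-ERP cohort generator that
    plants known templates, state sequences and condition effects at a
    controlled signal-to-noise ratio, so that every stage of the pipeline
    has a recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    rlang,
    stats,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
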
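Package: abfOverlap
Title: Bayesian Overlap Analysis of GWAS Summary Statistics
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies single-nucleotide polymorphisms associated with two
    epidemiologically linked traits from genome-wide association study (GWAS)
    summary statistics using approximate Bayes factors (ABFs). Provides the
    Wakefield-style ABF with a Normal effect-size prior, Bayesian decision
    rules theta = PO/R built from the prior probability of no association and
    a type II/type I error cost ratio, two-trait linkage-disequilibrium
    clumping metrics (ABF* and P*) that preferentially retain dual-trait
    signals, a McNemar mid-P test for overlap enrichment, a null-simulation
    engine that calibrates Bayes-factor decision rules to P-value thresholds
    per sample size (with quadratic log-regression extrapolation), and a power
    simulator comparing Bayesian and frequentist overlap detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    data.table,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'abf.R'
    'summary-io.R'
    'fixtures.R'
    'null-calibration.R'
    'overlap.R'
    'power.R'
    'cli.R'
    'utils.R'
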
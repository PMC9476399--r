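Package: phipbayes
Title: Bayesian Detection of Antibody-Reactive Peptides in PhIP-Seq Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects antibody-reactive peptides in Phage
    ImmunoPrecipitation Sequencing (PhIP-Seq) read-count data by comparing
    a serum sample against beads-only (mock immunoprecipitation) controls.
    Implements a Beta-Binomial spike-and-slab hierarchical Bayesian model
    fit by Markov chain Monte Carlo, three routes for estimating the
    beads-only Beta prior shape parameters (method of moments, constrained
    maximum likelihood, and empirical-Bayes dispersion-derived estimates),
    a negative-binomial exact-test comparator with one-sided p-values and
    Benjamini-Hochberg correction, a synthetic-data generator emulating
    PhIP-Seq count structure, and evaluation tools (interpolated ROC/PR
    curves, FDR-matched cutoffs, logistic power curves, round-robin
    false-positive assessment, and ranked-list concordance).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    edgeR,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
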
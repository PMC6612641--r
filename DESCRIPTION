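Package: ageswitch
Title: Two-Window Age-Trajectory Analysis of the Transcriptome with
    Connectivity Screening and Twin Heritability
Version: 0.1.0
Authors@R:
    person("ageswitch", "maintainers", email = "ageswitch@example.org",
           role = c("aut", "cre"))
Description: Tools for detecting and characterising a midlife "switch" in
    age-related transcript expression. Implements probe-level transcript
    quantification for 25-mer array probes (exact matching, single-match
    filtering, GC-content adjustment, detection filtering and median-polish
    summarisation), covariate-adjusted two-window Spearman age-association
    scans with cross-cohort consistency, Group 1 / Group 2 switch
    classification with coefficient-of-variation stochasticity controls and
    housekeeping-gene detection, cross-tissue direction concordance,
    connectivity-map style bidirectional Kolmogorov-Smirnov compound
    screening on a [-100, 100] scale, permutation-thresholded co-expression
    network node statistics, and monozygotic-twin intraclass-correlation
    heritability contrasts. Ships a synthetic-data generator that plants
    known trajectory classes, probe-level biases, twin panels and compound
    libraries for end-to-end recovery testing, plus a command-line pipeline
    driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
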
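Package: modbn
Title: Dynamic Bayesian Networks for Longitudinal Multi-Omics Microbiome Data
Version: 0.1.0
Authors@R:
    person("BioRG", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Temporal alignment and constraint-restricted two-slice dynamic
    Bayesian network (conditional linear-Gaussian) modelling for longitudinal
    multi-omics microbiome studies. Provides normalization and filtering of
    per-omic feature tables, B-spline trajectory fitting, linear time-warp
    alignment of subjects to an optimal reference, BIC-scored greedy structure
    learning over taxa, microbial genes, metabolites, host genes and
    environmental variables, subject-level bootstrap edge confidence,
    leave-one-subject-out forward prediction (MAE), and in-silico edge
    validation against interaction databases with an exact Poisson-binomial
    null and random-network baseline. Includes a seeded synthetic-data
    generator with known ground truth and a command-line pipeline driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
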
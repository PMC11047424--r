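Package: targetmr
Title: Drug-Target Mendelian Randomization with QTL Instruments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-sample Mendelian randomization for drug-target screens using
    cis-eQTL and pQTL summary statistics as instruments. Provides strict
    readers and validators for GWAS/QTL summary-statistic panels and LD
    matrices, instrument selection with p-value thresholds, greedy LD
    clumping, F-statistic and confounder filters, Wald-ratio and
    inverse-variance-weighted causal estimation with odds-ratio reporting and
    Bonferroni multiplicity control, Bayesian colocalization via per-SNP
    approximate Bayes factors with prior-sensitivity analysis, two-step MR
    mediation with proportion-mediated decomposition, and an LD-aware
    simulator of summary statistics with known causal structure for
    calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
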
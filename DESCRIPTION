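Package: protmr
Title: Proteome-Wide Mendelian Randomization and Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Two-sample Mendelian randomization for plasma-proteome screens
    against binary disease outcomes, from GWAS summary statistics. Implements
    pQTL instrument selection (genome-wide significance, weak-instrument and
    MHC filters, cis/trans assignment, sentinel selection, LD clumping,
    summary-statistic conditional analysis) and the four canonical instrument
    groupings; Wald-ratio, inverse-variance-weighted, Egger and weighted-median
    estimators with heterogeneity, Steiger directionality, leave-one-out and
    MR-PRESSO sensitivity analyses; binary-outcome statistical power;
    Benjamini-Hochberg discovery control with an independent-cohort
    replication rule; and single-causal-variant approximate-Bayes-factor
    colocalization used to flag MR hits confounded by linkage disequilibrium.
    A synthetic summary-statistics generator with exported ground truth makes
    the full discovery-replication-colocalization workflow testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
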
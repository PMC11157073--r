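Package: mrscreen
Title: Two-Sample Mendelian Randomization Screening from GWAS Summary
    Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomization (MR) causal
    screening from GWAS summary statistics: instrument selection by
    p-value thresholding, greedy LD clumping and F-statistic screening;
    allele harmonization with palindromic-SNP removal; five causal
    estimators (inverse-variance weighted, MR-Egger, weighted median,
    simple and weighted mode); heterogeneity and horizontal-pleiotropy
    diagnostics (Cochran's Q, I-squared, Egger intercept, MR-PRESSO,
    leave-one-out); two-step mediation MR with Sobel standard errors;
    reverse MR; Benjamini-Hochberg FDR control across many
    exposure-outcome pairs; a cis-eQTL instrument mode; and a synthetic
    summary-statistics generator with known causal structure for
    validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, yaml, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
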
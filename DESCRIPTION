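Package: cismr
Title: Proteome-Wide cis-Mendelian Randomization for Drug-Target Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample cis-Mendelian randomization pipeline for screening
    circulating proteins as candidate drug targets for binary disease outcomes.
    Provides summary-statistic ingestion and allele harmonization, cis-pQTL
    instrument selection (cis window, genome-wide significance, LD clumping,
    MHC exclusion) with instrument-strength diagnostics, Wald-ratio and
    inverse-variance-weighted causal estimation with Cochran's Q heterogeneity
    and false-discovery-rate control, Steiger directionality filtering,
    fixed- and random-effects replication meta-analysis with an I-squared
    model-selection rule, Bayesian colocalization via Wakefield approximate
    Bayes factors, evidence-based tier grading of targets, and an LD-aware
    summary-statistic simulator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
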
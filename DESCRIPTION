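Package: methylcause
Title: Smoking, Blood DNA Methylation and Lung Cancer: EWAS, Mediation
    and Two-Step Mendelian Randomization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested causal-inference pipeline linking a seven-level
    smoking phenotype, blood DNA methylation and lung cancer risk in
    nested case-control cohorts with two measurement waves.  Provides a
    synthetic-cohort generator with a fully known causal structure,
    per-CpG linear and logistic association scans with surrogate-variable
    adjustment, repeated-measures confirmation by cluster-robust pooled
    regression and random-intercept mixed models, counterfactual mediation
    with a weighted methylation score, and two-step Mendelian
    randomization (one-sample two-stage least squares via a smoking
    genetic score; two-sample Wald ratio and inverse-variance weighting
    over methylation quantitative trait loci, with cis-only filtering).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    lme4,
    yaml
Suggests:
    testthat (>= 3.0.0),
    sandwich,
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
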
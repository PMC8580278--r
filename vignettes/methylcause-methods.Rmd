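---
title: "Methods: simulated cohorts, association scans, mediation and Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated cohorts, association scans, mediation and Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylcause)
```

This vignette is the package's own account of its statistical machinery:
the generative model behind the synthetic cohorts, the estimators at each
stage of the smoking → DNA methylation → lung cancer chain, the numerical
conventions, and the design decisions that were genuinely open.

## The scientific setting

The analysis chain targets a nested case-control study of incident lung
cancer drawn from a population cohort with blood samples at two surveys
roughly eleven years apart. Methylation is measured as beta-values
(proportion methylated, in (0,1)) at CpG sites; smoking is summarized as a
seven-level ordinal phenotype (never; former split at ≤10.0 /
10.1–20.0 / ≥20.1 pack-years; current split the same way). The chain asks,
in order: which sites does smoking alter; are those associations stable
across repeated measurements; which sites associate with lung cancer; do
they *mediate* the smoking effect observationally; and does genetic
instrumentation (Mendelian randomization) support a causal
methylation→cancer link. The pipeline reproduces that logic on synthetic
cohorts with known truth, and all estimators also accept real tables
(phenotype CSV, methylation TSV, summary-statistic TSVs).

## The synthetic-cohort generative model

`simulate_cohort()` draws, in order:

1. **Genotypes.** Three smoking-associated SNPs (initiation, quantity,
   cessation proxies) as Binomial(2, f) dosages under Hardy–Weinberg;
   default frequencies 0.20/0.35/0.08. Per-CpG mQTL dosages are drawn the
   same way, 1–9 instruments per site with allelic effects
   γ ~ N(0, 0.15²) on the M-value scale.
2. **Smoking.** A latent liability b·(score) + N(0,1) cut at two
   thresholds into never/former/current. The weight b is calibrated by
   root-finding on a 20 000-individual pilot cohort (deterministic
   sub-seed) so that the regression R² of the realized 7-level phenotype
   on the raw allele-count score equals the configured target, 1.8% by
   default — a deliberately weak instrument, matching the first-stage
   strength this design realistically has. Calibrating the latent scale
   instead would undershoot after ordinal coarsening, which is why the
   pilot regression is run on the phenotype itself. Pack-years are
   Gamma(shape 2) with mean increasing in the quantity-SNP dosage and
   higher for current than former smokers; never-smokers have exactly 0.
3. **Methylation.** Site M-values are
   μ0 + τ·smoking + Σγ·dosage + cell term + batch term + u + ε, with τ
   the planted smoking effect (default −0.12 M per level at 76 signal
   sites, 80% negative / 20% positive to emulate predominant
   hypomethylation), a 6-component Dirichlet cell composition with
   per-site loadings, a two-level batch, a per-individual scalar
   intercept u ~ N(0, 0.20²) shared by both waves, and ε ~ N(0, 0.35²).
   Betas are 2^M/(2^M+1), strictly inside (0,1) by construction.
4. **Wave 2.** Status transitions follow a row-stochastic matrix with
   zero probability of returning to "never"; continuing smokers
   accumulate pack-years, quitters freeze them. Wave-2 methylation is
   regenerated from wave-2 exposure with the *same* u, which induces the
   within-person correlation the repeated-measures estimators rely on.
5. **Outcome and matching.** P(case) = logistic(α + θ_A·smoking +
   θ_M·mean mediator M-value), with α solved by `uniroot()` so the
   realized case fraction hits its target. Each case is greedily paired
   with the nearest-age unused same-sex control within a ±3-year
   caliper; failing that the caliper is doubled once, then the case is
   dropped with a warning. The matched-set id is recorded so both
   matched and unconditional analyses can be run.

The defaults θ_M = 0 and θ_A > 0 encode the structure the downstream
analyses are designed to detect: smoking alters methylation and causes
cancer, but methylation itself does not. Non-null θ_M settings exist for
power and recovery tests.

**What the generator does not emulate:** array-level artifacts (probe
chemistry, IDAT intensities), population stratification, fine-grained
cell-type deconvolution error (cell proportions are known by
construction), age-dependent methylation drift, and correlated CpG blocks
beyond the shared per-person intercept. Passing tests therefore certify
the estimators' statistical behaviour under the stated model, not
robustness to those real-data pathologies.

A note on the per-person intercept: it is a *scalar* per individual (a
rank-one, sample-level structure on the M scale), not a per-site random
effect. This keeps memory linear in cohort size and suffices for the
intraclass-correlation and sandwich-variance properties. It also has an
instructive consequence: surrogate-variable estimation residualizes the
exposure out before the SVD, so the (finite-sample) component of u that
is incidentally correlated with smoking cannot be recovered and remains a
small confounder. The scan's type-I calibration is therefore asserted
under a correctly specified null (latent intercept off, batch included or
SV-captured), and a separate check documents that SV adjustment removes
most — not all — of the latent-structure inflation at n ≈ 300.

## Exposure codings

The printed pack-year bands ("≤10.0", "10.1–20.0", "≥20.1") leave values
in (10.0, 10.1) and (20.0, 20.1) unassigned for non-grid reals; the
package uses the half-open convention ≤10.0 / (10.0, 20.0] / >20.0 and
documents it rather than asserting it as the source's rule. Ever-smokers
with missing pack-years get a missing phenotype and are excluded, not
imputed. The smoking-change coding maps current→former to *decrease*,
never→never and former→former to *no change*, and everything else —
including current→current, since exposure keeps accumulating — to
*increase*; transitions into "never" are rejected as data errors.

## Association scans

The linear EWAS is ordinary least squares of each site's beta-values on
[1, exposure, covariates, SVs], vectorized through one QR decomposition of
the shared design; p-values are two-sided t tests, flagged at the
epigenome-wide 5×10⁻⁸ and at Bonferroni p·m < 0.05. Exposure enters as a
numeric 0–6 linear term (the per-level effect the tables print), not as
dummies. p-values that underflow are reported as the smallest positive
double with that convention documented, never as zero.

Surrogate variables are the deterministic residual-SVD variant: betas are
residualized on exposure plus covariates, row-centered, and the top-k
right singular vectors returned, k = 12 by default; each column's sign is
fixed by making its largest-magnitude element positive. The
iteratively-reweighted SVA algorithm is deliberately not used — the
residual-SVD variant is reproducible bit-for-bit and testable against
planted batch vectors (recovery |r| > 0.95 in tests).

The logistic EWAS fits each site by maximum likelihood (IRLS with
convergence tolerance 10⁻⁸, 100 iterations); coefficients are reported
per full beta change 0→1, and `or_per_percent()` converts to the
odds-ratio-per-1% scale, exp(coef/100). Sites with perfect or
quasi-perfect separation (fitted probabilities at the boundary) are
returned with missing estimates and `converged = FALSE` rather than
aborting the scan. Whether smoking, cell counts and SVs enter this model
is caller-controlled; the mediator-screen variant leaves smoking out, the
direct-effect variant puts it in. The matched design is analyzed with
unconditional logistic regression adjusting for age and sex — the design
choice consistent with how the published odds ratios behave — and the
matched-set ids remain available for conditional analyses.

## Repeated measures

The pooled two-wave panel uses the wave-1 phenotype as exposure for both
rows of an individual (the confirmation question is whether baseline
smoking predicts methylation at both waves), with a wave indicator as
covariate for secular drift; both choices are toggleable. LMRSE point
estimates are exactly the pooled OLS estimates; only the variance is
robustified, with the CR1 sandwich G/(G−1)·(N−1)/(N−K)·(XᵀX)⁻¹[Σ_g
Xᵀ_g e_g eᵀ_g X_g](XᵀX)⁻¹ and p-values from t(G−1). CR1 with t(G−1) is
the standard choice at ~120 clusters; nothing in the source specifies the
small-sample correction, so it is asserted as this package's convention
and cross-checked in tests against both `sandwich::vcovCL` and a
2000-replicate cluster bootstrap (15% agreement band). With singleton
clusters the estimator reduces exactly to HC1.

The mixed-model cross-check fits a per-individual random intercept by
REML through `lme4::lmer`. On balanced two-wave panels with a
between-person exposure both estimators coincide with the person-mean OLS
estimator (a closed form used as the test oracle); the acceptance
property — LMRSE/LMEM coefficient correlation ≥ 0.97 over 1000 sites — is
asserted on a panel with 15% of wave-2 rows removed, since on a perfectly
balanced panel the correlation is trivially 1.

The change analysis regresses per-site Δbeta (wave 2 − wave 1) on the
numeric change code, unadjusted by default (a config switch adds
covariates), Bonferroni-corrected within the smoking-hit family.

## Mediation

Natural effects use the product method without exposure–mediator
interaction: NIE = θ_M·β₁·(a−a*), NDE = θ_A·(a−a*), TE = NDE + NIE on
the log-odds scale, with the exposure contrast (a, a*) = (1, 0), i.e.
per phenotype level. The decomposition identity NDE + NIE = TE is exact
by construction and asserted to machine precision. Confidence intervals
are percentile bootstrap (default B = 1000; B = 200 at pipeline scale)
over jointly refitted mediator and outcome models with nonparametric
resampling of individuals; a site is "identified" as a mediator when its
NIE interval excludes zero — no explicit selection rule was published,
so this conventional one is used and documented.

Two honesty caveats are built in. First, the case-control outcome is
~50% cases by design, so the product-method log-OR decomposition is a
rare-outcome approximation used *because the published relative effects
behave like ratios of the printed coefficients*; an independent
Monte-Carlo counterfactual estimator is cross-validated against it on
rare-outcome synthetic data in the tests. Second, with θ_M = 0 planted
the screen's "identified" sites are false positives at roughly the
nominal CI error rate — the tests assert this, which is precisely the
cautionary point about observational mediation that the MR step then
adjudicates. The weighted methylation score is Σ_j w_j·β_ij with w the
smoking-unadjusted cancer-EWAS coefficients of the identified sites,
analyzed as a single mediator.

The relative indirect effect NIE/TE is reported as undefined (NA), never
infinite, when |TE| < 10⁻¹⁰.

## Mendelian randomization

The first step instruments smoking with the unweighted 3-SNP allele
score (no published weighting exists). `instrument_strength()` reports
R² and F = R²/(1−R²)·(n−2); 2SLS regresses the exposure on the score,
then the site M-value on the fitted exposure, with the standard 2SLS
variance using residuals recomputed at the observed exposure.
Weak-instrument results (F below 10) are flagged but reported — the
design this emulates reported through F = 2.4 — and the tests verify
both the just-identified Wald-ratio identity and unbiasedness under
planted unmeasured confounding where OLS is demonstrably biased.

The second step is two-sample MR over mQTL instruments: the Wald ratio
Γ/γ with first-order SE se_Γ/|γ| for single instruments, fixed-effect
IVW otherwise (random-effects IVW is deliberately omitted: 1–9
instruments per site make heterogeneity estimates fragile). Allele
harmonization matches by SNP id, sign-flips swapped or strand-flipped
alleles, resolves palindromic SNPs by allele frequency when both
frequencies are at least 0.08 away from 0.5, and drops ambiguous
palindromes with a warning. The cis filter keeps instruments on the
CpG's chromosome within an inclusive 1 Mb window — the cis/trans
boundary is not defined in the source, so 1 Mb (the field's usual mQTL
convention) is asserted as a package default. Per-instrument variance
explained uses 2f(1−f)γ²/var(M). Sites with no usable instruments or no
outcome statistics are reported as untestable rather than silently
dropped.

## Numerical conventions and seeds

- Beta↔M conversion uses 1/(1+2^(−m)), stable in both tails; beta inputs
  outside (0,1) raise an error unless an explicit clamp at ε = 10⁻⁶ is
  requested.
- All linear algebra goes through QR; rank-deficient designs abort with
  the collinear columns named.
- One global seed fans out to per-stage sub-seeds via a multiplicative
  congruential mix (seed·48271 + k·69621 + 1013904223 mod 2³¹−1) so that
  stages are independently reproducible and nested derivations cannot
  collide with sibling streams — a plain additive offset does collide,
  which is why the mix is multiplicative. Identical config and seed give
  byte-identical cohorts, scans and bootstrap intervals.
- The logistic boundary tolerance for declaring separation is fitted
  probabilities within 10⁻¹⁰ of 0 or 1.

## Problem sizes in the test suite

The suite exercises: cohorts of 120–5000 individuals; scans over up to
1000 sites (type-I calibration at n = 300, 1000 null sites); 2SLS
coverage over 500 confounded replicates of n = 1500; 1500 null
summary-statistic replicates for the second-step screen; 1000-site
LMRSE-vs-LMEM comparison on a 124-person panel; and mediation bootstraps
of 100–300 replicates. These sizes were chosen so the statistical bands
(binomial Monte-Carlo error, 2-SE recovery) are sharp enough to detect
real estimator defects while the full suite stays comfortably within a
desktop run.

## Known limitations

- Beta-scale linear models are heteroscedastic by construction (the
  noise is Gaussian on the M scale); the scans quantify association as
  the published analysis did rather than modelling the variance, and the
  M-scale path is available wherever effects are planted linearly.
- The product-method mediation decomposition is exact only under the
  no-interaction, rare-outcome regime; the prevalence-weighted
  alternative is a documented estimator choice, not a default.
- Fixed-effect IVW assumes no directional pleiotropy; no Egger or
  median estimators are provided because the emulated analysis used
  none.
- The greedy nearest-age matching is not optimal matching; with tight
  calipers and small pools it can drop cases where an optimal assignment
  would not.
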
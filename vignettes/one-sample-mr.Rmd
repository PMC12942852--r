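---
title: "Methods: individual-level MR of triglycerides on hypertension"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-level MR of triglycerides on hypertension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind `tgmr`, the design
decisions that were genuinely open, the synthetic-cohort generator and what
it does and does not emulate, and the numerical conventions used throughout.

## 1. The estimation problem

The estimand is the effect of log triglycerides on hypertension risk in a
single cross-sectional cohort, expressed as an odds ratio per one-unit
increase in *genetically predicted* ln(TG). The design is one-sample MR:
instruments are discovered, weighted and used within the same individuals,
which buys a shared confounding structure for the observational/MR contrast
at the price of winner's-curse and weak-instrument hazards. The package's
machinery exists largely to manage those hazards explicitly:

* instrument screening is prespecified and audited (strength, covariate
  independence, no direct outcome association);
* every estimate carries its first-stage F and partial R²;
* the genetic risk score (GRS) has a K-fold cross-fitted variant whose
  weights never see the fold they score;
* an overidentified linear 2SLS companion model enables Sargan and
  Wu–Hausman diagnostics that the logistic primary model cannot provide.

## 2. Estimators

With first stage `ln_tg ~ instrument + age + sex + bmi` (complete cases,
male as the sex reference level):

* **2SPS** fits `htn ~ fitted(ln_tg) + covariates` by logistic regression.
  With a nonlinear second stage this is an approximation — the fitted
  coefficient is not exactly the conditional log-odds effect — which is why
  2SRI is always reported alongside.
* **2SRI** fits `htn ~ ln_tg + firstStageResidual + covariates`; the
  residual is the raw (additive) first-stage residual, the standard control
  function for a linear exposure model. The residual coefficient doubles as
  an endogeneity probe and parallels the Wu–Hausman test.
* **2SLS** treats `htn` as a linear probability. Covariates are included
  instruments; classical standard errors are the default so that the Sargan
  statistic (n·R² of residuals regressed on all instruments and covariates,
  χ² with #instruments − 1 df) and the Wu–Hausman augmented regression have
  their textbook forms. Heteroskedasticity-robust (HC0) errors are available
  behind a flag but are not the default, precisely because the diagnostic
  suite assumes the classical forms.

With a *linear* second stage, 2SPS, 2SRI and 2SLS are algebraically one
estimator for a single endogenous exposure; the test suite verifies the
three code paths agree to 1e-10 on random instances. Crude models drop the
covariates from both stages; adjusted models use age + sex + BMI in both.
Second-stage uncertainty is Wald by default; a nonparametric case-resampling
bootstrap that reruns both stages per replicate is available
(`bootstrapCi`), since the appropriate 2SPS variance is otherwise
model-dependent.

## 3. Screening rules and their known behavior

Candidates come from an additive scan of ln(TG) adjusted for age and sex at
the suggestive threshold p < 1e-5 (genome-wide significance is unattainable
in a single cohort of this size; the scan and weighting covariate sets are
deliberately separate configuration). Screening then applies, per candidate:

1. orientation so the first-stage β (and hence the GRS weight) is positive;
2. partial F > 10;
3. independence from age, sex and BMI (linear regressions; logistic for
   sex) at α = 0.05 — the threshold is configurable since only the checks,
   not their level, are conventionally fixed;
4. no covariate-adjusted direct association with hypertension at α = 0.05,
   with a significant *negative* coefficient on a TG-increasing allele
   labeled `direction_inconsistent`.

Rule 4 is deliberately conservative: an instrument whose exposure effect is
strong enough that its downstream causal effect is visible per allele will
fail it even when perfectly valid. That behavior is intended (it mirrors the
prespecified-safeguard philosophy) and is documented in the tests rather
than patched away. Negative-control regressions of instruments on other
biomarkers are computed with nominal p-values and are reporting-only — they
never feed selection.

## 4. The synthetic cohort generator

The generator is first-class, tested code. It emulates the statistical
structure the analysis assumes, not any real individual's data:

* **Genotypes**: independent Binomial(2, MAF) per variant (Hardy–Weinberg),
  default instrument MAFs (0.05, 0.15, 0.20), 500 null markers at MAF
  0.05–0.5. There is no linkage disequilibrium beyond optional duplicated
  columns used to exercise pruning, and no population structure.
* **Covariates**: age ~ Normal(50, 10) truncated to 20–86 years, 40% male,
  BMI ~ Normal(24 + 0.02·(age − 50), 3) kg/m². These are descriptive
  stand-ins; only their confounding role matters for the tests.
* **Exposure**: ln(TG) = 4.78 + Σ βⱼGⱼ + 0.004·age_c − 0.15·female +
  0.02·BMI_c + γ_U·U + ε, with U ~ N(0,1) an unmeasured confounder and the
  per-allele effects fixed at the adjusted first-stage values
  (0.145, 0.069, 0.072 ln-units).
* **Outcome**: Bernoulli with logit θ₀ + θ_TG·ln(TG) + 0.05·age_c −
  0.65·female + 0.17·BMI_c + θ_U·U + Σ δₚ·Gₚ. The intercept θ₀ is
  calibrated to the 25.2% prevalence target by monotone root-finding on a
  fixed 1e5 Monte-Carlo draw with an internal fixed seed — exact under any
  parameter combination, deterministic regardless of the session RNG, and
  cached across replicates.
* **Consistency**: blood-pressure readings and the medication flag are drawn
  conditionally on the outcome so the 140/90/medication classification rule
  holds row by row; the confounder U lives only in the truth record, never
  in the analysis-facing table.

**Residual-variance calibration.** The residual SD of ln(TG) (0.49 in the
unconfounded scenarios; 0.4214 under confounding so that the genetic + U +
noise budget is unchanged) is chosen so the *combined* three-SNP score
explains ≈ 2.0% of exposure variance after covariates — the weak-instrument
regime the analysis is designed around (combined partial F ≈ 43 at
n = 2159). A note on an alternative that does not exist: with the per-allele
effects and MAFs above, the ratios of per-SNP explained variances are fixed
by βⱼ²·2·MAFⱼ(1 − MAFⱼ), so no single residual SD can place *each* SNP's
partial R² in a narrow band around 0.01; calibrating the combined score to
0.020 puts the individual SNPs at ≈ 0.008 / 0.005 / 0.007. The combined
figure is the one the downstream precision argument rests on, so it anchors
the calibration.

**Scenarios.** `null` (θ_TG = 0, no confounding), `causal`
(θ_TG = ln 2), `confounded_null` (θ_TG = 0 but γ_U = 0.25, θ_U = 0.6, so
the crude observational OR exceeds 1.1 while the truth is null) and
`pleiotropic` (causal plus a direct δ = 0.4 log-odds-per-allele effect of
the first instrument on the outcome). The δ was sized by a noncentrality
calculation so that both the Sargan test and the direct-association screen
detect the violation with ≈ 0.9 power at n = 1e4 — a planted violation the
diagnostics cannot see would test nothing.

**What passing tests do not show.** Real cohorts have LD, assortative
structure, genotyping error, non-lognormal TG tails, medication-induced
selection and covariate measurement error; none are modeled. Calibration
results on this generator demonstrate internal statistical correctness of
the estimators and diagnostics, not robustness to those features.

## 5. Cross-fitting and how it is evaluated

`crossfitGrs` assigns outcome-stratified folds (default K = 10,
seed-controlled), estimates per-SNP weights and orientations on the other
folds, and scores each fold out-of-fold. One subtlety is worth recording:
under the null (no true SNP effects), testing the pooled out-of-fold score
against the exposure across *all* individuals is still anticonservative,
because each individual's exposure noise enters the weights used to score
the other folds; empirically the pooled test rejects at roughly twice the
nominal level even though each score is honestly out-of-fold. The correctly
calibrated construction — exposed as `foldwiseAssociation()` — tests the
association within each held-out fold, where the weights are independent of
the evaluation data and the regression p-value is exact. The in-sample
weighted score, by contrast, shows the full winner's-curse inflation; the
test suite demonstrates both facts.

## 6. Numerical conventions and degenerate inputs

* Natural logarithms throughout; nonpositive values become missing and are
  counted, never silently dropped.
* HOMA-IR converts glucose mg/dL → mmol/L with divisor 18.016.
* Complete-case analysis per model fit; no imputation anywhere. Different
  estimates may therefore use slightly different n, which every estimate
  records.
* Logistic fits: IRLS with epsilon 1e-10, max 100 iterations; complete
  separation raises an explicit error. Wald 95% intervals use z = 1.959964;
  all tests are two-sided at α = 0.05.
* Exact HWE test: conditional enumeration via the heterozygote-ladder
  recurrence computed on the log scale (long ladders would overflow raw
  probabilities), p = Σ P(config) ≤ P(observed) with a 1 + 1e-12 tie
  guard; a χ² variant sits behind a flag.
* LD pruning removes the *later* variant of an offending pair (position,
  then id) — equivalently keeps the first seen, matching the common
  tool convention; the window parameter is in variants, not kb.
* QC order: sample call rate → marker call rate → MAF → HWE; pruning only at
  instrument selection. Filters are idempotent.
* Constant dosage columns yield flagged undefined scan statistics and a
  `degenerate` screening rejection, never a crash; a deterministic first
  stage (zero residual variance) makes Wu–Hausman error out explicitly.
* All randomness flows from explicit seeds; fold assignment, calibration
  and simulation each use derived child seeds kept within 32-bit range.

## 7. Test-suite problem sizes

Calibration suites use 500 replicates at n = 2159 for the type-I error of
the 2SPS Wald test under the confounded null; 1000 replicates at n = 2000
(linear outcome, where the classical n·R² form is exact) for Sargan
uniformity; 100 replicates at n = 1e4 for diagnostic power; 200 replicates
at n = 1e4 for 2SLS recovery under strengthened instruments (first-stage
R² ≈ 0.3); 40 replicates at n = 2159 for the weak-instrument
wide-interval property; and 500 replicates at n = 500 with eight null
markers for the cross-fitting contrast. These sizes were chosen to give the
binomial/Monte-Carlo bounds quoted in the tests comfortable resolution on a
single core.

## 8. Known limitations

* Two-sample / summary-statistic MR, MR-Egger, weighted-median and
  MR-PRESSO are out of scope: with three cohort-specific instruments the
  multi-instrument pleiotropy-robust estimators are not applicable.
* The 2SPS logistic second stage is an approximation; treat the OR scale as
  interpretive convention, and lean on 2SRI/2SLS concordance.
* The sex chromosomes receive no special handling (autosomal analysis is
  assumed), and binary genotype formats (BED/BGEN/VCF) are not parsed —
  dosage export is expected upstream.
* The generator's independence assumptions (no LD) mean pruning is
  exercised only on constructed correlated columns.
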
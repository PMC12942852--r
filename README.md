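# tgmr — individual-level Mendelian randomization for triglycerides and hypertension

Observational studies consistently find that people with elevated circulating
triglycerides (TG) are more likely to be hypertensive, but that association is
vulnerable to confounding (age, sex, adiposity, shared cardiometabolic
dysregulation) and reverse causation. One-sample Mendelian randomization (MR)
addresses this by using genetic variants as instrumental variables: because
alleles are assigned at conception, a variant that raises ln(TG) and satisfies
the instrumental-variable assumptions shifts hypertension risk only through
its effect on TG.

`tgmr` implements the full individual-level analysis pipeline for this design,
aimed at epidemiologists and statistical geneticists working with cohort-scale
(n in the low thousands) genotype + phenotype data:

* **Data model and QC** — typed containers for phenotype tables and additive
  dosage matrices (PLINK `.raw` dialect supported), derived variables
  (natural-log transforms, HOMA-IR, the 140/90/medication hypertension rule),
  and genotype QC: call-rate filters (0.90 sample / 0.95 marker), MAF ≥ 0.01,
  exact Hardy–Weinberg test at p ≥ 0.001, and windowed LD pruning
  (250-variant window, step 50, r² ≤ 0.5) applied only at instrument
  selection.
* **Instrument discovery and screening** — an additive per-SNP scan of
  ln(TG) adjusted for age and sex with a suggestive threshold (p < 1e-5),
  followed by prespecified screening with a machine-readable audit trail:
  instrument strength (partial F > 10, with partial R² = F/(F + df)),
  independence from age/sex/BMI, and absence of a direct covariate-adjusted
  association with hypertension (including the direction-inconsistency rule
  for TG-increasing alleles that lower outcome odds).
* **Genetic risk scores** — weighted allele scores with first-stage
  β weights, K-fold cross-fitted (out-of-fold weighted) scores to remove
  within-cohort weight optimism, and an expanded sensitivity-only score.
* **Causal estimators and diagnostics** — two-stage predictor substitution
  (2SPS, the primary estimator for the binary outcome), two-stage residual
  inclusion (2SRI control function), overidentified linear two-stage least
  squares (2SLS) with Sargan and Wu–Hausman tests, bootstrap intervals, and
  weak-instrument reporting on every estimate.
* **Observational arm** — Student t and Pearson chi-square comparisons,
  covariate-adjusted comparisons (with explicit not-applicable markers),
  crude/adjusted logistic odds ratios, and a forest-style table contrasting
  observational and MR estimates.
* **Synthetic cohort generator** — a fully parameterized generative model
  (HWE genotypes, log-normal exposure with small per-allele effects,
  confounded binary outcome calibrated to 25.2% prevalence) with named
  scenarios (`null`, `causal`, `confounded_null`, `pleiotropic`), so every
  stage is testable without access to individual-level cohort data.

## The model

First stage (per instrument or score, complete cases):

    ln(TG)_i = alpha + beta * G_i + gamma' C_i + e_i,      C = (age, sex, BMI)

with instrument strength summarized by the partial F (= t² for one
parameter) and partial R² = t² / (t² + df). Second stage (2SPS):

    logit P(HTN_i = 1) = theta0 + theta * ln(TG)_i^hat + delta' C_i

so exp(theta) is the odds ratio per one-unit increase in genetically
predicted ln(TG). 2SRI instead enters the observed exposure plus the
first-stage residual; 2SLS treats hypertension as a linear probability and,
with ≥ 2 instruments, supports the Sargan overidentification test
(n·R² of the residual-on-instruments regression, df = #instruments − 1) and
the Wu–Hausman endogeneity test.

## Worked example

```r
library(tgmr)
cfg <- simulationConfig("causal", seed = 7L, nNullSnps = 0L)
sim <- simulateCohort(cfg)
sim$cohort
#> Cohort with 2159 individuals and 15 columns
#>   hypertension prevalence: 24.3%
#>   derived columns: ln_tg, homa_ir

g <- dosages(sim$genotypes)
w <- sapply(1:3, function(j) instrumentStrength(g[, j], sim$cohort)$beta)
score <- drop(g[, 1:3] %*% w)
twoStagePS(sim$cohort, score, label = "GRS")
#> 2SPS [GRS, adjusted] OR = 1.95 (95% CI 0.61-6.29), p = 0.262, n = 2159
#>   first stage: F = 67.9, partial R2 = 0.031

obs <- logisticOr(sim$cohort, "ln_tg", covars = c("age", "sex", "bmi"))
#> observational adjusted OR = 2.51 (95% CI 2.01-3.13), p = 3.64e-16
```

The contrast is the design's point: with weak instruments at this sample
size the MR interval is wide and crosses the null even though the generating
causal odds ratio is 2, while the observational association is sharp. The
`runPipeline()` orchestrator runs the whole chain (simulate/load → QC → scan
→ screen → GRS/cross-fit → 2SPS/2SRI/2SLS + diagnostics → observational arm
→ forest table) and writes per-stage artifacts plus a re-runnable manifest.

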
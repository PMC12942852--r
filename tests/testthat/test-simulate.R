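test_that("genotype generator respects allele frequency and determinism", {
  g <- simulateGenotypes(1e4, c(0.5, 0.1), seed = 3)
  f1 <- mean(dosages(g)[, 1]) / 2
  expect_lt(abs(f1 - 0.5), 3 * sqrt(0.5 * 0.5 / (2 * 1e4)))
  f2 <- mean(dosages(g)[, 2]) / 2
  expect_lt(abs(f2 - 0.1), 3 * sqrt(0.1 * 0.9 / (2 * 1e4)))

  expect_identical(dosages(simulateGenotypes(50, c(0.2), seed = 9)),
                   dosages(simulateGenotypes(50, c(0.2), seed = 9)))
  # near-zero MAF column is valid
  g3 <- simulateGenotypes(100, 1e-6, seed = 1)
  expect_true(all(dosages(g3) %in% c(0, 1, 2)))
  expect_error(simulateGenotypes(10, 0.6, seed = 1), "0.5")
})

test_that("generated genotype columns are consistent with HWE", {
  g <- simulateGenotypes(500, runif(200, 0.05, 0.5), seed = 21)
  p <- apply(dosages(g), 2, function(col)
    hweExactP(sum(col == 2), sum(col == 1), sum(col == 0)))
  expect_gte(mean(p >= 0.001), 0.99)
})

test_that("exposure model reduces to its null and degenerate forms", {
  n <- 5000
  cfg0 <- simulationConfig("null", n = n, instrumentBetas = c(0, 0, 0),
                           gammaAge = 0, gammaSex = 0, gammaBmi = 0)
  g <- simulateGenotypes(n, cfg0@instrumentMafs, seed = 5,
                         ids = paste0("iv", 1:3))
  cov <- tgmr:::simulateCovariates(n, 6)
  lntg <- simulateExposure(g, cov, cfg0, seed = 8)
  expect_lt(abs(mean(lntg) - cfg0@alpha0), 3 * cfg0@sigmaEps / sqrt(n))

  # sigmaEps = 0 with a single unit effect: exact genotype-group differences
  cfg1 <- simulationConfig("causal", n = 30, instrumentMafs = 0.5,
                           instrumentBetas = 1, sigmaEps = 0,
                           gammaAge = 0, gammaSex = 0, gammaBmi = 0)
  g1 <- simulateGenotypes(30, 0.5, seed = 2, ids = "iv1")
  cov1 <- tgmr:::simulateCovariates(30, 3)
  lntg1 <- simulateExposure(g1, cov1, cfg1, seed = 4)
  expect_equal(as.vector(tapply(lntg1, dosages(g1)[, 1], mean)),
               cfg1@alpha0 + sort(unique(dosages(g1)[, 1])),
               tolerance = 1e-12)
})

test_that("per-SNP exposure variance matches the analytic decomposition", {
  n <- 1e5
  cfg <- simulationConfig("causal", n = n)
  g <- simulateGenotypes(n, cfg@instrumentMafs, seed = 31,
                         ids = paste0("iv", 1:3))
  cov <- tgmr:::simulateCovariates(n, 32)
  lntg <- simulateExposure(g, cov, cfg, seed = 33)
  resid <- lm(lntg ~ cov$age + cov$sex + cov$bmi)$residuals
  vres <- var(resid)
  for (j in 1:3) {
    maf <- cfg@instrumentMafs[j]
    analytic <- cfg@instrumentBetas[j]^2 * 2 * maf * (1 - maf) / vres
    fit <- lm(resid ~ dosages(g)[, j])
    r2 <- summary(fit)$r.squared
    expect_lt(abs(r2 - analytic), 0.003)
  }
})

test_that("intercept calibration hits the target prevalence", {
  flat <- simulationConfig("null", instrumentBetas = c(0, 0, 0),
                           gammaAge = 0, gammaSex = 0, gammaBmi = 0,
                           thetaAge = 0, thetaSex = 0, thetaBmi = 0,
                           sigmaEps = 0.3)
  expect_equal(calibrateIntercept(
    simulationConfig("null", instrumentBetas = c(0, 0, 0),
                     gammaAge = 0, gammaSex = 0, gammaBmi = 0,
                     thetaAge = 0, thetaSex = 0, thetaBmi = 0,
                     sigmaEps = 0.3, targetPrevalence = 0.5)), 0,
    tolerance = 1e-6)
  expect_equal(calibrateIntercept(flat), qlogis(544 / 2159), tolerance = 1e-6)

  # causal preset: realized prevalence within half a point at n = 1e5
  cfg <- simulationConfig("causal", n = 1e5, nNullSnps = 0L, seed = 17L)
  sim <- simulateCohort(cfg)
  expect_gte(sim$truth$realizedPrevalence, 0.247)
  expect_lte(sim$truth$realizedPrevalence, 0.257)
})

test_that("outcome model plants and withholds effects as configured", {
  # theta_TG = ln 2: a large-n logistic refit on the true exposure recovers it
  n <- 1e5
  cfg <- simulationConfig("causal", n = n)
  g <- simulateGenotypes(n, cfg@instrumentMafs, seed = 41,
                         ids = paste0("iv", 1:3))
  cov <- tgmr:::simulateCovariates(n, 42)
  lntg <- simulateExposure(g, cov, cfg, seed = 43)
  th0 <- calibrateIntercept(cfg)
  htn <- simulateOutcome(lntg, g, cov, cfg, th0, seed = 44)
  fit <- glm(htn ~ lntg + cov$age + cov$sex + cov$bmi, family = binomial())
  est <- coef(summary(fit))["lntg", ]
  expect_lt(abs(est["Estimate"] - log(2)), 3 * est["Std. Error"])

  # pleiotropic scenario: the flagged SNP associates with the outcome
  # conditional on covariates
  cfgP <- simulationConfig("pleiotropic", n = n)
  lntgP <- simulateExposure(g, cov, cfgP, seed = 45)
  htnP <- simulateOutcome(lntgP, g, cov, cfgP, calibrateIntercept(cfgP),
                          seed = 46)
  fitP <- glm(htnP ~ dosages(g)[, 1] + cov$age + cov$sex + cov$bmi,
              family = binomial())
  expect_lt(coef(summary(fitP))[2, "Pr(>|z|)"], 1e-4)
})

test_that("cohort simulation is reproducible and prevalence-calibrated", {
  cfg <- simulationConfig("causal", n = 2159, nNullSnps = 10L, seed = 77L)
  s1 <- simulateCohort(cfg)
  s2 <- simulateCohort(cfg)
  expect_identical(cohortData(s1$cohort), cohortData(s2$cohort))
  expect_identical(dosages(s1$genotypes), dosages(s2$genotypes))
  expect_gte(s1$truth$realizedPrevalence, 0.22)
  expect_lte(s1$truth$realizedPrevalence, 0.28)
  # classification rule holds row by row in the generated table
  d <- cohortData(s1$cohort)
  expect_identical(classifyHypertension(d$sbp, d$dbp, d$on_htn_med), d$htn)
  # the confounder never reaches the analysis-facing table
  expect_false(any(c("u", "U") %in% names(d)))
})

test_that("confounded-null preset inflates the crude observational OR", {
  cfg <- simulationConfig("confounded_null", n = 1e5, nNullSnps = 0L,
                          seed = 99L)
  sim <- simulateCohort(cfg)
  crude <- logisticOr(sim$cohort, "ln_tg")
  expect_gt(crude$or, 1.1)
  expect_equal(sim$truth$thetaTG, 0)
  # adjusting for the withheld confounder and the shared covariates (both
  # confound by construction) restores the null
  d <- cohortData(sim$cohort)
  fit <- glm(htn ~ ln_tg + u + age + sex + bmi, family = binomial(),
             data = cbind(d, u = sim$truth$u))
  est <- coef(summary(fit))["ln_tg", ]
  expect_lt(abs(est["Estimate"]), 3 * est["Std. Error"] + 0.02)
})

test_that("missingness injection matches its rate and mask determinism", {
  g <- simulateGenotypes(200, rep(0.3, 50), seed = 8)
  expect_identical(dosages(injectMissingness(g, 0, seed = 1)), dosages(g))
  gm <- injectMissingness(g, 0.5, seed = 2)
  rate <- mean(is.na(dosages(gm)))
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / length(dosages(g))))
  expect_identical(dosages(injectMissingness(g, 0.5, seed = 2)), dosages(gm))
  expect_error(injectMissingness(g, 1), "rate")
})
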
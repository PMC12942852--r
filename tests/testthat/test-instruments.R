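test_that("instrument strength arithmetic follows the partial F/R2 identities", {
  # F = 21.2 with df = 2149 - 5 rounds to partial R2 = 0.010
  expect_equal(round(partialR2FromF(21.2, 2149 - 5), 3), 0.010)
  expect_equal(partialR2FromF(0, 100), 0)

  # nested-model oracle at n = 30: t^2 equals the F comparing
  # ln_tg ~ covars against ln_tg ~ dosage + covars
  set.seed(23)
  n <- 30
  dose <- rbinom(n, 2, 0.4)
  d <- data.frame(sample_id = sprintf("S%03d", 1:n),
                  age = rnorm(n, 50, 10),
                  sex = sample(c("male", "female"), n, TRUE),
                  bmi = rnorm(n, 24, 3))
  d$ln_tg <- 4.7 + 0.3 * dose + 0.01 * d$age + rnorm(n, 0, 0.4)
  ch <- makeCohort(d)
  st <- instrumentStrength(dose, ch)
  f0 <- lm(ln_tg ~ age + sex + bmi, data = cohortData(ch))
  f1 <- lm(ln_tg ~ dose + age + sex + bmi, data = cohortData(ch))
  fnested <- anova(f0, f1)$F[2]
  expect_equal(st$f, fnested, tolerance = 1e-8)
  expect_equal(st$partialR2, st$f / (st$f + n - 5), tolerance = 1e-12)
})

test_that("partial R2 is increasing in F and saturates at 1", {
  fs <- c(0, 0.5, 2, 10, 50, 1e6)
  r2 <- partialR2FromF(fs, df = 2000)
  expect_true(all(diff(r2) > 0))
  expect_equal(r2[1], 0)
  expect_gt(r2[6], 0.99)
})

test_that("covariate-independence screen detects planted dependence", {
  set.seed(31)
  n <- 600
  age <- rnorm(n, 50, 10)
  ch <- makeCohort(data.frame(
    sample_id = sprintf("S%04d", 1:n), age = age,
    sex = sample(c("male", "female"), n, TRUE), bmi = rnorm(n, 24, 3),
    ln_tg = rnorm(n, 4.7, 0.5), htn = runif(n) < 0.25))
  planted <- pmin(pmax(round(age / 40), 0), 2)  # dosage built from age
  rows <- checkCovariateIndependence(planted, ch, id = "aged")
  expect_false(rows$pass[rows$check == "independence_age"])
  expect_identical(rows$reason[rows$check == "independence_age"],
                   "covariate_dependent")
  # constant dosage: every check degenerate
  rows2 <- checkCovariateIndependence(rep(1, n), ch, id = "const")
  expect_true(all(!rows2$pass))
  expect_true(all(rows2$reason == "degenerate"))
})

test_that("independence screen false-positive rate matches its level", {
  set.seed(32)
  fails <- vapply(1:200, function(s) {
    n <- 300
    ch <- makeCohort(data.frame(
      sample_id = sprintf("S%04d", 1:n), age = rnorm(n, 50, 10),
      sex = sample(c("male", "female"), n, TRUE), bmi = rnorm(n, 24, 3)))
    dose <- rbinom(n, 2, 0.3)
    any(!checkCovariateIndependence(dose, ch, id = "x")$pass)
  }, logical(1))
  expected <- 1 - 0.95^3
  expect_lt(abs(mean(fails) - expected),
            3 * sqrt(expected * (1 - expected) / 200))
})

test_that("direct-outcome screen flags pleiotropy and direction inconsistency", {
  sim <- plantedSim(n = 1e4, seed = 3, scenario = "pleiotropic")
  dose <- dosages(sim$genotypes)[, "iv1"]
  row <- checkOutcomeDirect(dose, sim$cohort, id = "iv1")
  expect_false(row$pass)
  expect_identical(row$reason, "direct_association")

  # a TG-increasing allele that lowers outcome odds is labeled
  # direction-inconsistent
  cfg <- simulationConfig("pleiotropic", n = 1e4, seed = 4L, nNullSnps = 0L,
                          pleiotropyDelta = c(-0.4, 0, 0))
  simNeg <- simulateCohort(cfg)
  rowNeg <- checkOutcomeDirect(dosages(simNeg$genotypes)[, "iv1"],
                               simNeg$cohort, id = "iv1")
  expect_false(rowNeg$pass)
  expect_identical(rowNeg$reason, "direction_inconsistent")
})

test_that("null instruments pass the direct-outcome screen at ~1 - alpha", {
  set.seed(33)
  pass <- vapply(1:120, function(s) {
    cfg <- simulationConfig("null", n = 800, instrumentBetas = c(0, 0, 0),
                            nNullSnps = 0L, seed = as.integer(4000 + s))
    sim <- simulateCohort(cfg)
    checkOutcomeDirect(dosages(sim$genotypes)[, "iv2"], sim$cohort,
                       id = "iv2")$pass
  }, logical(1))
  expect_lt(abs(mean(pass) - 0.95), 3 * sqrt(0.95 * 0.05 / 120) + 0.01)
})

test_that("instrument screening keeps good candidates and audits all failures", {
  # strengthened instruments so the strength rule is comfortably met; the
  # confounded-null preset keeps the instruments valid (no outcome path
  # through the exposure, so the direct screen stays at its nominal level)
  cfg <- simulationConfig("confounded_null", n = 4000, seed = 8L,
                          nNullSnps = 2L,
                          instrumentBetas = c(0.2, 0.15, 0.15),
                          instrumentMafs = c(0.2, 0.3, 0.3))
  sim <- simulateCohort(cfg)
  instr <- selectInstruments(sim$genotypes, sim$cohort,
                             c("iv1", "iv2", "iv3", "null1"), alpha = 0.01)
  tab <- instrumentTable(instr)
  expect_true(all(c("iv1", "iv2", "iv3") %in% tab$id))
  expect_false("null1" %in% tab$id)
  expect_true(all(tab$weight > 0))
  aud <- auditTrail(instr)
  expect_true(all(c("iv1", "iv2", "iv3", "null1") %in% aud$id))
  # the null candidate fails on strength
  expect_identical(aud$reason[aud$id == "null1" & aud$check == "strength"],
                   "weak")
  expect_error(selectInstruments(sim$genotypes, sim$cohort, "null2"),
               "no valid instruments")
  expect_error(selectInstruments(sim$genotypes, sim$cohort, character(0)),
               "no valid instruments")
})

test_that("screening orients weights positive for exposure-lowering alleles", {
  cfg <- simulationConfig("confounded_null", n = 4000, seed = 9L,
                          nNullSnps = 0L,
                          instrumentBetas = c(-0.25, 0.2, 0.2),
                          instrumentMafs = c(0.3, 0.3, 0.3))
  sim <- simulateCohort(cfg)
  instr <- selectInstruments(sim$genotypes, sim$cohort, c("iv1", "iv2"))
  tab <- instrumentTable(instr)
  expect_true(all(tab$weight > 0))
  expect_true(tab$flipped[tab$id == "iv1"])
  # oriented counted allele is the other allele of the pair
  v <- variantInfo(sim$genotypes)
  expect_identical(tab$counted_allele[tab$id == "iv1"],
                   v$ref[v$id == "iv1"])
})

test_that("GRS is the weighted allele count on complete cases", {
  d <- matrix(c(0, 1, 2, 1, 0,
                2, 2, 0, 1, 1,
                1, 0, 1, 2, NA), ncol = 3)
  g <- makeGenotypes(d)
  iv <- new("InstrumentSet",
            variants = data.frame(id = c("v1", "v2", "v3"),
                                  counted_allele = "G", flipped = FALSE,
                                  weight = c(0.145, 0.069, 0.072),
                                  beta = c(0.145, 0.069, 0.072),
                                  se = 0.02, f_stat = 20, partial_r2 = 0.01,
                                  n_used = 5L, sensitivity_only = FALSE),
            audit = data.frame(id = c("v1", "v2", "v3"), check = "strength",
                               statistic = 20, p = NA, pass = TRUE,
                               reason = ""),
            covariateSet = c("age", "sex", "bmi"))
  grs <- buildGrs(g, iv)
  s <- scoreVector(grs)
  expect_equal(length(s), 4)  # S005 dropped: missing v3
  hand <- d[1:4, ] %*% c(0.145, 0.069, 0.072)
  expect_equal(unname(s), drop(hand), tolerance = 1e-12)

  # unit weights give the plain allele count
  iv1 <- iv
  iv1@variants$weight <- rep(1, 3)
  expect_equal(unname(scoreVector(buildGrs(g, iv1))),
               unname(rowSums(d))[1:4])
})

test_that("in-sample GRS R2 is at least each single-instrument R2", {
  sim <- plantedSim(n = 3000, seed = 12)
  instr <- selectInstruments(sim$genotypes, sim$cohort,
                             c("iv1", "iv2", "iv3"), fMin = 0, alpha = 1e-6)
  grs <- buildGrs(sim$genotypes, instr)
  d <- cohortData(sim$cohort)
  s <- scoreVector(grs)[d$sample_id]
  r2 <- function(x) summary(lm(d$ln_tg ~ x))$r.squared
  grsR2 <- r2(s)
  for (id in instrumentTable(instr)$id)
    expect_gte(grsR2 + 1e-10, r2(dosages(sim$genotypes)[, id]))
})

test_that("cross-fitted GRS is deterministic, guarded, and tracks in-sample
           scores when weights are homogeneous", {
  cfg <- simulationConfig("causal", n = 1200, seed = 21L, nNullSnps = 0L,
                          instrumentBetas = c(0.4, 0.35, 0.3),
                          instrumentMafs = c(0.3, 0.3, 0.3),
                          sigmaEps = 0.05)
  sim <- simulateCohort(cfg)
  cf1 <- crossfitGrs(sim$genotypes, sim$cohort, c("iv1", "iv2", "iv3"),
                     seed = 5)
  cf2 <- crossfitGrs(sim$genotypes, sim$cohort, c("iv1", "iv2", "iv3"),
                     seed = 5)
  expect_identical(scoreVector(cf1), scoreVector(cf2))
  expect_identical(cf1@foldId, cf2@foldId)
  expect_identical(cf1@weightProvenance, "out-of-fold")

  instr <- selectInstruments(sim$genotypes, sim$cohort,
                             c("iv1", "iv2", "iv3"), fMin = 0, alpha = 1e-9)
  insample <- buildGrs(sim$genotypes, instr)
  shared <- intersect(names(scoreVector(cf1)), names(scoreVector(insample)))
  expect_gt(cor(scoreVector(cf1)[shared], scoreVector(insample)[shared]),
            0.99)

  expect_error(crossfitGrs(sim$genotypes, sim$cohort, c("iv1"), K = 1200),
               "cross-fitting|fold")
})

test_that("expanded score adds a sensitivity-only variant and flags it", {
  cfg <- simulationConfig("pleiotropic", n = 5000, seed = 31L, nNullSnps = 0L,
                          instrumentMafs = c(0.3, 0.3, 0.3, 0.25),
                          instrumentBetas = c(0.3, 0.2, 0.2, 0.25),
                          thetaTG = 0, pleiotropyDelta = c(0, 0, 0, 0.5))
  sim <- simulateCohort(cfg)
  instr <- selectInstruments(sim$genotypes, sim$cohort,
                             c("iv1", "iv2", "iv3"))
  exp_set <- expandedGrs(sim$genotypes, sim$cohort, instr, "iv4")
  tab <- instrumentTable(exp_set)
  expect_true("iv4" %in% tab$id)
  expect_true(tab$sensitivity_only[tab$id == "iv4"])
  aud <- auditTrail(exp_set)
  expect_true(any(aud$check == "sensitivity_inclusion" &
                  grepl("bypasses_direct_check", aud$reason)))

  # joint first-stage partial F strictly increases with the strong extra SNP
  d <- cohortData(sim$cohort)
  grs0 <- scoreVector(buildGrs(sim$genotypes, instr))[d$sample_id]
  grs1 <- scoreVector(buildGrs(sim$genotypes, exp_set,
                               includeSensitivity = TRUE))[d$sample_id]
  f0 <- instrumentStrength(grs0, sim$cohort)$f
  f1 <- instrumentStrength(grs1, sim$cohort)$f
  expect_gt(f1, f0)

  # a weak extra variant is refused
  cfgW <- simulationConfig("causal", n = 3000, seed = 32L, nNullSnps = 1L)
  simW <- simulateCohort(cfgW)
  instrW <- selectInstruments(simW$genotypes, simW$cohort, c("iv1", "iv2"),
                              fMin = 0, alpha = 1e-9)
  expect_error(expandedGrs(simW$genotypes, simW$cohort, instrW, "null1"),
               "strength")
})

test_that("negative-control scan is reporting-only with calibrated p-values", {
  set.seed(41)
  pvals <- numeric(0)
  for (s in 1:60) {
    n <- 400
    ch <- makeCohort(data.frame(
      sample_id = sprintf("S%04d", 1:n), age = rnorm(n, 50, 10),
      sex = sample(c("male", "female"), n, TRUE), bmi = rnorm(n, 24, 3),
      ln_tg = rnorm(n, 4.7, 0.5), htn = runif(n) < 0.25,
      marker = rnorm(n)))
    g <- makeGenotypes(matrix(rbinom(n, 2, 0.3), ncol = 1))
    iv <- new("InstrumentSet",
              variants = data.frame(id = "v1", counted_allele = "G",
                                    flipped = FALSE, weight = 0.1, beta = 0.1,
                                    se = 0.02, f_stat = 25, partial_r2 = 0.01,
                                    n_used = n, sensitivity_only = FALSE),
              audit = data.frame(id = "v1", check = "strength", statistic = 25,
                                 p = NA, pass = TRUE, reason = ""),
              covariateSet = c("age", "sex", "bmi"))
    pvals <- c(pvals, negativeControlScan(iv, g, ch, "marker")$p)
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)

  # the exposure itself shows up loudly (sanity), and empty input is empty
  sim <- plantedSim(n = 3000, seed = 5,
                    instrumentBetas = c(0.3, 0.2, 0.2),
                    instrumentMafs = c(0.3, 0.3, 0.3))
  instr <- selectInstruments(sim$genotypes, sim$cohort, c("iv1", "iv2", "iv3"),
                             fMin = 0, alpha = 1e-9)
  sanity <- negativeControlScan(instr, sim$genotypes, sim$cohort, "ln_tg",
                                covars = c("age", "sex"))
  expect_true(any(sanity$p < 1e-6))
  expect_equal(nrow(negativeControlScan(instr, sim$genotypes, sim$cohort,
                                        character(0))), 0)
})
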
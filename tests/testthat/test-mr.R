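test_that("first stage reproduces a perfect instrument and the F identity", {
  sim <- plantedSim(n = 1500, seed = 2)
  d <- cohortData(sim$cohort)
  # instrument equal to the exposure: fitted = exposure, residuals 0
  fs <- suppressWarnings(firstStage(sim$cohort, d$ln_tg, covars = character(0)))
  expect_equal(fs$fitted, d$ln_tg, tolerance = 1e-10)
  expect_lt(max(abs(fs$residuals)), 1e-10)

  # F equals the squared t of the instrument coefficient
  g <- dosages(sim$genotypes)[, "iv1"]
  fsg <- suppressWarnings(firstStage(sim$cohort, g))
  expect_equal(fsg$f, unname(fsg$fit$statistic["instrument"])^2,
               tolerance = 1e-12)
  expect_equal(fsg$partialR2, fsg$f / (fsg$f + fsg$fit$df_residual),
               tolerance = 1e-12)
})

test_that("a weak first stage warns but never refuses", {
  set.seed(3)
  n <- 500
  ch <- makeCohort(data.frame(
    sample_id = sprintf("S%04d", 1:n), age = rnorm(n, 50, 10),
    sex = sample(c("male", "female"), n, TRUE), bmi = rnorm(n, 24, 3),
    ln_tg = rnorm(n, 4.7, 0.5), htn = runif(n) < 0.25))
  z <- rbinom(n, 2, 0.3)  # unrelated to the exposure
  expect_warning(fs <- firstStage(ch, z), "weak instrument")
  expect_true(is.list(fs))
})

test_that("2SPS, 2SRI and 2SLS coincide exactly with a linear second stage", {
  set.seed(7)
  worst <- 0
  for (rep in 1:20) {
    n <- 120
    z <- rbinom(n, 2, 0.3)
    u <- rnorm(n)
    x <- 0.3 * z + 0.5 * u + rnorm(n)
    y <- 0.7 * x - 0.6 * u + rnorm(n)
    age <- rnorm(n, 50, 10)
    W <- cbind(`(Intercept)` = 1, age = age)
    ch <- makeCohort(data.frame(sample_id = sprintf("S%04d", 1:n), age = age,
                                sex = "male", bmi = 24, ln_tg = x, htn = y))
    # package 2SLS
    est <- suppressWarnings(twoSls(ch, z, covars = "age", outcome = "htn"))
    # linear 2SPS: OLS of y on first-stage fitted values
    fs <- olsFit(cbind(W, z = z), x)
    b_ps <- olsFit(cbind(xhat = fs$fitted, W), y)$coefficients["xhat"]
    # linear 2SRI: OLS of y on x and the first-stage residual
    b_ri <- olsFit(cbind(x = x, v = fs$residuals, W), y)$coefficients["x"]
    worst <- max(worst, abs(est@estimate - b_ps), abs(est@estimate - b_ri))
  }
  expect_lt(worst, 1e-10)
})

test_that("2SLS equals OLS under a perfect instrument and the ratio form", {
  set.seed(8)
  n <- 200
  x <- rnorm(n)
  y <- 0.5 * x + rnorm(n)
  ch <- makeCohort(data.frame(sample_id = sprintf("S%04d", 1:n),
                              age = rnorm(n, 50, 10), sex = "male", bmi = 24,
                              ln_tg = x, htn = y))
  est <- suppressWarnings(twoSls(ch, x, covars = character(0),
                                 outcome = "htn"))
  ols <- olsFit(cbind(1, x = x), y)
  expect_equal(est@estimate, unname(ols$coefficients["x"]), tolerance = 1e-10)

  # 10-row instance: the covariate-residualized ratio closed form
  z10 <- c(0, 1, 2, 0, 1, 2, 1, 0, 2, 1)
  a10 <- c(45, 52, 58, 49, 61, 50, 47, 55, 53, 60)
  x10 <- c(4.2, 4.8, 5.3, 4.4, 5.0, 5.5, 4.6, 4.3, 5.6, 4.9)
  y10 <- c(0, 0, 1, 0, 1, 1, 0, 0, 1, 1)
  ch10 <- makeCohort(data.frame(sample_id = sprintf("S%03d", 1:10), age = a10,
                                sex = "male", bmi = 24, ln_tg = x10,
                                htn = y10))
  est10 <- suppressWarnings(twoSls(ch10, z10, covars = "age",
                                   outcome = "htn"))
  W <- cbind(1, a10)
  rz <- z10 - W %*% solve(t(W) %*% W, t(W) %*% z10)
  ry <- y10 - W %*% solve(t(W) %*% W, t(W) %*% y10)
  rx <- x10 - W %*% solve(t(W) %*% W, t(W) %*% x10)
  expect_equal(est10@estimate, sum(rz * ry) / sum(rz * rx), tolerance = 1e-10)
})

test_that("2SLS recovers a known slope with strong instruments", {
  set.seed(9)
  n <- 2e4
  z <- sapply(c(0.3, 0.3, 0.3), function(m) rbinom(n, 2, m))
  u <- rnorm(n)
  x <- 4.7 + z %*% c(0.4, 0.3, 0.3) + 0.5 * u + rnorm(n, 0, 0.5)
  y <- drop(0.5 * x - 0.7 * u + rnorm(n))
  ch <- makeCohort(data.frame(sample_id = sprintf("S%06d", 1:n),
                              age = rnorm(n, 50, 10), sex = "male", bmi = 24,
                              ln_tg = drop(x), htn = y))
  zl <- list(iv1 = z[, 1], iv2 = z[, 2], iv3 = z[, 3])
  est <- twoSls(ch, zl, covars = character(0), outcome = "htn")
  se <- (est@ciHigh - est@ciLow) / (2 * 1.959964)
  expect_lt(abs(est@estimate - 0.5), 3 * se)
  # OLS is confounded away from 0.5; 2SLS corrects it
  ols <- olsFit(cbind(1, x = drop(x)), y)
  expect_gt(abs(unname(ols$coefficients["x"]) - 0.5), 0.05)
})

test_that("2SRI residual coefficient mirrors exposure endogeneity", {
  # exogenous exposure: residual coefficient near zero, Wu-Hausman quiet
  sim <- plantedSim(n = 4000, seed = 13,
                    instrumentBetas = c(0.3, 0.25, 0.25),
                    instrumentMafs = c(0.3, 0.3, 0.3))
  g <- dosages(sim$genotypes)[, "iv1"]
  ri <- twoStageRI(sim$cohort, g, label = "iv1")
  expect_gt(ri@detail$residual_p, 0.001)

  # strong confounding: Wu-Hausman rejects loudly at n = 1e4
  simC <- plantedSim(n = 1e4, seed = 14, scenario = "confounded_null",
                     gammaU = 0.45, thetaU = 1.2,
                     instrumentBetas = c(0.3, 0.25, 0.25),
                     instrumentMafs = c(0.3, 0.3, 0.3))
  zl <- lapply(c("iv1", "iv2", "iv3"),
               function(i) dosages(simC$genotypes)[, i])
  names(zl) <- c("iv1", "iv2", "iv3")
  wh <- wuHausmanTest(simC$cohort, zl)
  expect_lt(wh$p, 1e-4)
})

test_that("Sargan test guards identification and powers against pleiotropy", {
  sim <- plantedSim(n = 3000, seed = 15,
                    instrumentBetas = c(0.3, 0.25, 0.25),
                    instrumentMafs = c(0.3, 0.3, 0.3))
  g1 <- dosages(sim$genotypes)[, "iv1"]
  just <- twoSls(sim$cohort, g1)
  expect_error(sarganTest(just), "df = 0")

  zl <- lapply(c("iv1", "iv2", "iv3"),
               function(i) dosages(sim$genotypes)[, i])
  names(zl) <- c("iv1", "iv2", "iv3")
  over <- twoSls(sim$cohort, zl)
  sg <- sarganTest(over)
  expect_equal(sg$df, 2)
  expect_true(sg$p >= 0 && sg$p <= 1)
})

test_that("Wu-Hausman errors on a deterministic first stage", {
  n <- 100
  z <- rbinom(n, 2, 0.4)
  ch <- makeCohort(data.frame(sample_id = sprintf("S%04d", 1:n),
                              age = rnorm(n, 50, 10), sex = "male", bmi = 24,
                              ln_tg = 0.5 * z, htn = rnorm(n)))
  expect_error(suppressWarnings(
    wuHausmanTest(ch, z, covars = character(0))), "degenerate")
})

test_that("bootstrap interval is percentile-based, deterministic and guarded", {
  est <- function(idx) 1.0  # degenerate estimator
  ci <- bootstrapCi(est, n = 50, B = 200, seed = 4)
  expect_equal(ci$ciLow, ci$ciHigh)

  set.seed(10)
  x <- rnorm(300)
  mn <- function(idx) mean(x[idx])
  c1 <- bootstrapCi(mn, n = 300, B = 300, seed = 9)
  c2 <- bootstrapCi(mn, n = 300, B = 300, seed = 9)
  expect_identical(c1$estimates, c2$estimates)
  expect_lt(c1$ciLow, mean(x)); expect_gt(c1$ciHigh, mean(x))
  expect_error(bootstrapCi(mn, n = 300, B = 50, seed = 1), "at least 100")
  bad <- function(idx) stop("nope")
  expect_error(bootstrapCi(bad, n = 10, B = 100, seed = 1), "failed")
})

test_that("mean 2SLS estimate increases with the true causal slope", {
  set.seed(77)
  grid <- c(0, 0.4, 0.8)
  means <- sapply(grid, function(theta) {
    mean(replicate(25, {
      n <- 1500
      z <- sapply(c(0.3, 0.3, 0.3), function(m) rbinom(n, 2, m))
      u <- rnorm(n)
      x <- drop(4.7 + z %*% c(0.3, 0.25, 0.25) + 0.4 * u + rnorm(n, 0, 0.45))
      y <- theta * x - 0.5 * u + rnorm(n)
      ch <- makeCohort(data.frame(sample_id = sprintf("S%05d", 1:n),
                                  age = 50, sex = "male", bmi = 24,
                                  ln_tg = x, htn = y))
      zl <- list(iv1 = z[, 1], iv2 = z[, 2], iv3 = z[, 3])
      twoSls(ch, zl, covars = character(0), outcome = "htn")@estimate
    }))
  })
  expect_true(all(diff(means) > 0))
})
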
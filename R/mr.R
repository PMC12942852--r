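# Resolve an instrument argument (named vector, GrsVector, or plain vector)
# to a numeric vector aligned with the cohort rows, NA where unavailable.
resolveInstrument <- function(cohort, instrument) {
  d <- cohortData(cohort)
  if (methods::is(instrument, "GrsVector")) {
    s <- scoreVector(instrument)
    out <- s[match(d$sample_id, names(s))]
    names(out) <- d$sample_id
    return(out)
  }
  if (!is.null(names(instrument))) {
    out <- instrument[match(d$sample_id, names(instrument))]
    names(out) <- d$sample_id
    return(out)
  }
  if (length(instrument) != nrow(d))
    stop("unnamed instrument vector must match the cohort length")
  instrument
}

#' First-stage exposure regression
#'
#' Linear regression of ln(TG) on the instrument (a SNP dosage or a genetic
#' risk score) plus covariates, on complete cases. Returns the fit together
#' with fitted values, residuals and the weak-instrument statistics. An F at
#' or below 10 produces a warning, never an error: the engine reports weak
#' instruments, it does not refuse them.
#'
#' @param cohort Cohort with ln_tg (and htn for downstream stages).
#' @param instrument dosage vector, named score vector or GrsVector.
#' @param covars covariate names (default age, sex, BMI; character(0) for the
#'   crude model).
#' @return list(fit, fitted, residuals, rows, f, partialR2, n).
#' @export
firstStage <- function(cohort, instrument, covars = c("age", "sex", "bmi")) {
  d <- cohortData(cohort)
  z <- resolveInstrument(cohort, instrument)
  rows <- completeRows(d, c("ln_tg", "htn", covars), z)
  if (length(rows) < length(covars) + 3) stop("too few complete cases")
  dd <- d[rows, , drop = FALSE]
  X <- designMatrix(dd, covars, focal = list(instrument = z[rows]))
  fit <- olsFit(X, dd$ln_tg)
  t <- unname(fit$statistic["instrument"])
  f <- t^2
  if (f <= 10)
    warning(sprintf("weak instrument: first-stage F = %.2f (<= 10)", f))
  list(fit = fit, fitted = fit$fitted, residuals = fit$residuals, rows = rows,
       f = f, partialR2 = f / (f + fit$df_residual), n = fit$n)
}

mkEstimate <- function(method, label, model, estimate, se, n, covars,
                       f = NA_real_, r2 = NA_real_, logScale = TRUE,
                       detail = list(), seMethod = "wald",
                       ci = NULL, p = NULL) {
  p <- p %||% (2 * stats::pnorm(abs(estimate / se), lower.tail = FALSE))
  if (logScale) {
    ciL <- ci %||% c(exp(estimate - Z975 * se), exp(estimate + Z975 * se))
    orv <- exp(estimate)
  } else {
    ciL <- ci %||% c(estimate - Z975 * se, estimate + Z975 * se)
    orv <- NA_real_
  }
  methods::new("MrEstimate", method = method, label = label, model = model,
               estimate = estimate, orValue = orv, ciLow = ciL[1],
               ciHigh = ciL[2], p = p, firstStageF = f, firstStageR2 = r2,
               n = as.integer(n),
               covariateSet = if (length(covars)) covars else "none",
               seMethod = seMethod, detail = detail)
}

#' Two-stage predictor substitution (2SPS)
#'
#' The primary individual-level MR estimator for a binary outcome: the
#' genetically predicted ln(TG) from the first stage replaces the observed
#' exposure in a second-stage logistic regression of hypertension. The
#' reported OR is per one-unit increase in genetically predicted ln(TG).
#' With a nonlinear second stage this is an approximation; 2SRI is the
#' prespecified robustness companion.
#'
#' @param cohort Cohort.
#' @param instrument dosage vector, named score vector or GrsVector.
#' @param covars covariates used in both stages (character(0) = crude).
#' @param label instrument label for reporting.
#' @return an \code{\linkS4class{MrEstimate}}.
#' @export
twoStagePS <- function(cohort, instrument, covars = c("age", "sex", "bmi"),
                       label = "instrument") {
  fs <- firstStage(cohort, instrument, covars)
  d <- cohortData(cohort)[fs$rows, , drop = FALSE]
  X2 <- designMatrix(d, covars, focal = list(pred_lntg = fs$fitted))
  fit2 <- logisticFit(X2, as.numeric(d$htn))
  mkEstimate("2SPS", label, if (length(covars)) "adjusted" else "crude",
             unname(fit2$coefficients["pred_lntg"]),
             unname(fit2$se["pred_lntg"]), fs$n, covars,
             f = fs$f, r2 = fs$partialR2,
             detail = list(first_stage = fs))
}

#' Two-stage residual inclusion (2SRI, control function)
#'
#' Second-stage logistic regression of hypertension on the observed ln(TG)
#' plus the first-stage residual (the control function) and covariates; the
#' causal estimate is the observed-exposure coefficient. The residual
#' coefficient is retained in the detail slot — its Wald test parallels the
#' Wu-Hausman endogeneity test.
#'
#' @inheritParams twoStagePS
#' @return an \code{\linkS4class{MrEstimate}}.
#' @export
twoStageRI <- function(cohort, instrument, covars = c("age", "sex", "bmi"),
                       label = "instrument") {
  fs <- firstStage(cohort, instrument, covars)
  d <- cohortData(cohort)[fs$rows, , drop = FALSE]
  X2 <- designMatrix(d, covars,
                     focal = list(ln_tg = d$ln_tg, fs_resid = fs$residuals))
  fit2 <- logisticFit(X2, as.numeric(d$htn))
  mkEstimate("2SRI", label, if (length(covars)) "adjusted" else "crude",
             unname(fit2$coefficients["ln_tg"]), unname(fit2$se["ln_tg"]),
             fs$n, covars, f = fs$f, r2 = fs$partialR2,
             detail = list(first_stage = fs,
                           residual_coef = unname(fit2$coefficients["fs_resid"]),
                           residual_p = unname(fit2$p["fs_resid"])))
}

#' Linear two-stage least squares (2SLS)
#'
#' Standard 2SLS with the covariates as included instruments; with a binary
#' outcome this is a linear probability model, used as the overidentified
#' sensitivity specification that enables the Sargan and Wu-Hausman tests.
#' With a single excluded instrument the estimate equals the ratio
#' cov(z~, y) / cov(z~, x) on covariate-residualized variables. Classical
#' standard errors by default (making the diagnostic tests textbook-exact);
#' heteroskedasticity-robust (HC0) errors behind a flag.
#'
#' @param cohort Cohort.
#' @param instruments a named list of dosage vectors, a matrix with one
#'   column per instrument, or a single vector / GrsVector.
#' @param covars covariate names.
#' @param robust use HC0 robust standard errors (default FALSE).
#' @param label reporting label.
#' @param outcome outcome column (default "htn", entered as 0/1).
#' @return an \code{\linkS4class{MrEstimate}} whose estimate is the
#'   risk-difference slope per ln(TG) unit; the detail slot carries what the
#'   diagnostic tests need.
#' @export
twoSls <- function(cohort, instruments, covars = c("age", "sex", "bmi"),
                   robust = FALSE, label = "instruments", outcome = "htn") {
  d <- cohortData(cohort)
  if (methods::is(instruments, "GrsVector") || is.atomic(instruments) &&
      !is.matrix(instruments))
    instruments <- list(iv = instruments)
  if (is.matrix(instruments))
    instruments <- stats::setNames(
      lapply(seq_len(ncol(instruments)), function(j) instruments[, j]),
      colnames(instruments) %||% paste0("iv", seq_len(ncol(instruments))))
  zmat <- sapply(instruments, function(z) resolveInstrument(cohort, z))
  zmat <- matrix(zmat, ncol = length(instruments),
                 dimnames = list(NULL, names(instruments)))

  ok <- completeRows(d, c("ln_tg", outcome, covars))
  ok <- ok[rowSums(is.na(zmat[ok, , drop = FALSE])) == 0]
  dd <- d[ok, , drop = FALSE]
  Z <- zmat[ok, , drop = FALSE]
  y <- as.numeric(dd[[outcome]])
  x <- dd$ln_tg
  W <- designMatrix(dd, covars)                 # intercept + covariates
  Zfull <- cbind(W, Z)

  qz <- qr(Zfull)
  if (qz$rank < ncol(Zfull)) stop("first-stage design is rank deficient")
  xhat <- qr.fitted(qz, x)
  fsFit <- olsFit(Zfull, x)

  X2 <- cbind(ln_tg = xhat, W)
  qr2 <- qr(X2)
  beta <- qr.coef(qr2, y)
  resid_struct <- y - drop(cbind(ln_tg = x, W) %*% beta)  # residual at actual x
  n <- length(y); p2 <- ncol(X2)
  XtXinv <- chol2inv(qr.R(qr2))
  dimnames(XtXinv) <- list(colnames(X2), colnames(X2))
  if (robust) {
    meat <- crossprod(X2 * resid_struct)
    vc <- XtXinv %*% meat %*% XtXinv
  } else {
    sigma2 <- sum(resid_struct^2) / (n - p2)
    vc <- sigma2 * XtXinv
  }
  se <- sqrt(diag(vc))
  est <- unname(beta["ln_tg"])
  sed <- unname(se["ln_tg"])
  tstat <- est / sed
  p <- 2 * stats::pt(abs(tstat), n - p2, lower.tail = FALSE)

  fsF <- if (ncol(Z) == 1) unname(fsFit$statistic[colnames(Z)[1]])^2 else {
    # joint F for the excluded instruments: nested-model comparison
    fit0 <- olsFit(W, x)
    ((fit0$rss - fsFit$rss) / ncol(Z)) / (fsFit$rss / fsFit$df_residual)
  }
  r2 <- {
    fit0 <- olsFit(W, x)
    (fit0$rss - fsFit$rss) / fit0$rss
  }

  mkEstimate("2SLS", label, if (length(covars)) "adjusted" else "crude",
             est, sed, n, covars, f = fsF, r2 = r2, logScale = FALSE,
             p = p,
             detail = list(residuals = resid_struct, Z = Z, W = W, x = x,
                           y = y, n = n, n_instruments = ncol(Z),
                           first_stage_fit = fsFit))
}

#' Sargan overidentification test
#'
#' Regresses the 2SLS structural residuals on all instruments and covariates;
#' the statistic n R^2 is chi-squared with (#instruments - 1) degrees of
#' freedom under the joint null that all instruments are valid. Rejection
#' signals instrument disagreement — possible pleiotropy. Requires an
#' overidentified model.
#'
#' @param est a 2SLS \code{\linkS4class{MrEstimate}}.
#' @return list(stat, df, p).
#' @export
sarganTest <- function(est) {
  dt <- est@detail
  if (is.null(dt$n_instruments)) stop("sarganTest needs a twoSls() result")
  df <- dt$n_instruments - 1
  if (df < 1)
    stop("just-identified model: df = 0, Sargan test undefined")
  aux <- olsFit(cbind(dt$W, dt$Z), dt$residuals)
  r2 <- aux$r_squared
  stat <- dt$n * r2
  list(stat = stat, df = df, p = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Wu-Hausman endogeneity test
#'
#' Augmented regression: the outcome on the observed exposure, the
#' first-stage residual and the covariates (linear outcome scale); the t test
#' of the residual coefficient. Rejection indicates the exposure is
#' endogenous, i.e. OLS and IV disagree beyond sampling noise.
#'
#' @param cohort Cohort.
#' @param instruments as in \code{\link{twoSls}}.
#' @param covars covariate names.
#' @param outcome outcome column (default "htn").
#' @return list(stat (F = t^2), p, df).
#' @export
wuHausmanTest <- function(cohort, instruments, covars = c("age", "sex", "bmi"),
                          outcome = "htn") {
  est <- twoSls(cohort, instruments, covars, outcome = outcome)
  dt <- est@detail
  vhat <- dt$x - dt$first_stage_fit$fitted
  if (stats::var(vhat) < 1e-14)
    stop("first-stage residual is degenerate (zero variance); test undefined")
  aug <- olsFit(cbind(ln_tg = dt$x, vhat = vhat, dt$W), dt$y)
  t <- unname(aug$statistic["vhat"])
  list(stat = t^2, p = 2 * stats::pt(abs(t), aug$df_residual, lower.tail = FALSE),
       df = aug$df_residual)
}

#' Nonparametric bootstrap percentile interval
#'
#' Case-resampling bootstrap re-running the full estimator (both stages) on
#' each replicate; percentile 95% interval. Errors out if more than 5% of
#' replicates fail.
#'
#' @param statistic function(rowIndices) -> numeric scalar, re-fitting the
#'   estimator on the resampled rows.
#' @param n number of rows in the data being resampled.
#' @param B number of replicates (default 1000, minimum 100).
#' @param seed RNG seed.
#' @return list(ciLow, ciHigh, estimates, failures).
#' @export
bootstrapCi <- function(statistic, n, B = 1000, seed = 1) {
  if (B < 100) stop("B must be at least 100")
  draws <- withSeed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(statistic(idx), error = function(e) NA_real_)
    }, numeric(1))
  })
  failures <- sum(is.na(draws))
  if (failures > 0.05 * B)
    stop("estimator failed in ", failures, " of ", B, " bootstrap replicates")
  qs <- stats::quantile(draws, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  list(ciLow = qs[1], ciHigh = qs[2], estimates = draws, failures = failures)
}
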
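#' Independent two-sample t test
#'
#' Equal-variance (Student) t test by default — the default of the software
#' family the baseline comparisons mirror — with Welch behind a flag.
#'
#' @param values numeric vector (on the analysis scale; ln where flagged).
#' @param group two-level factor or logical.
#' @param welch use the Welch correction (default FALSE).
#' @return list(t, df, p).
#' @export
ttestIndependent <- function(values, group, welch = FALSE) {
  g <- factor(group)
  if (nlevels(g) != 2) stop("group must have exactly two levels")
  tt <- stats::t.test(values ~ g, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction (matching the convention of the software family
#' whose output the baseline table mirrors); df = 1.
#'
#' @param counts 2x2 matrix of nonnegative counts with positive margins.
#' @param correct apply the Yates correction (default FALSE).
#' @return list(stat, df, p).
#' @export
chi2Test <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in contingency table")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(stat = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
}

#' Covariate-adjusted group comparison
#'
#' Linear model variable ~ group + covariates on the analysis scale; the
#' adjusted p-value is the Wald p of the group coefficient, and adjusted
#' means are model predictions per group at the grand covariate means. When
#' the variable is itself a member of the covariate set the comparison is
#' not applicable and an explicit marker is returned instead of a number.
#'
#' @param cohort Cohort.
#' @param variable column name (analysis scale, e.g. "ln_tg").
#' @param group grouping column (default "htn").
#' @param covars adjustment covariates (default age, sex, BMI).
#' @return list(adjustedMeans (length 2), p, applicable) — with
#'   applicable = FALSE and NAs when the variable is in the covariate set.
#' @export
adjustedCompare <- function(cohort, variable, group = "htn",
                            covars = c("age", "sex", "bmi")) {
  base <- sub("^ln_", "", variable)
  if (variable %in% covars || base %in% covars || variable == group)
    return(list(adjustedMeans = c(NA_real_, NA_real_), p = NA_real_,
                applicable = FALSE))
  d <- cohortData(cohort)
  rows <- completeRows(d, c(variable, group, covars))
  dd <- d[rows, , drop = FALSE]
  gind <- as.numeric(dd[[group]])
  X <- designMatrix(dd, covars, focal = list(group = gind))
  fit <- olsFit(X, dd[[variable]])
  cm <- colMeans(X)
  at0 <- cm; at0["group"] <- 0
  at1 <- cm; at1["group"] <- 1
  list(adjustedMeans = c(sum(at0 * fit$coefficients),
                         sum(at1 * fit$coefficients)),
       p = unname(fit$p["group"]), applicable = TRUE)
}

#' Crude or adjusted logistic odds ratio
#'
#' Logistic regression of the outcome on the variable (univariable when
#' \code{covars} is NULL, multivariable otherwise) through the package's
#' logistic engine. For ln-transformed variables the OR is per one-unit
#' increase of the ln value.
#'
#' @param cohort Cohort.
#' @param variable predictor column name (analysis scale). A factor variable
#'   (e.g. sex) enters as its indicator.
#' @param covars NULL (crude) or covariate names (adjusted).
#' @param outcome outcome column (default "htn").
#' @return list(or, ciLow, ciHigh, p, n, estimate, se).
#' @export
logisticOr <- function(cohort, variable, covars = NULL, outcome = "htn") {
  d <- cohortData(cohort)
  covars <- covars %||% character(0)
  rows <- completeRows(d, c(variable, outcome, covars))
  dd <- d[rows, , drop = FALSE]
  v <- dd[[variable]]
  if (is.factor(v)) v <- as.numeric(v) - 1  # indicator for the second level
  X <- designMatrix(dd, setdiff(covars, variable),
                    focal = stats::setNames(list(v), variable))
  fit <- logisticFit(X, as.numeric(dd[[outcome]]))
  list(or = unname(fit$or[variable]),
       ciLow = unname(fit$ci_low[variable]),
       ciHigh = unname(fit$ci_high[variable]),
       p = unname(fit$p[variable]), n = fit$n,
       estimate = unname(fit$coefficients[variable]),
       se = unname(fit$se[variable]))
}

#' Baseline comparison table
#'
#' One row per variable: descriptive means +/- standard errors per outcome
#' group on the original scale, the unadjusted test (Student t on the
#' analysis scale for continuous variables, chi-square for factors) and the
#' covariate-adjusted p. Variables flagged \code{ln} are analyzed on the
#' natural-log scale while displayed on the original scale.
#'
#' @param cohort Cohort.
#' @param variableSpec data.frame(variable, ln_flag) naming cohort columns;
#'   ln-flagged variables must have positive values.
#' @param group outcome column (default "htn").
#' @param covars adjustment covariates.
#' @return data.frame with columns variable, mean0, se0, mean1, se1, p,
#'   p_adjusted, ln_flag, applicable.
#' @export
baselineTable <- function(cohort, variableSpec, group = "htn",
                          covars = c("age", "sex", "bmi")) {
  if (!nrow(variableSpec))
    return(data.frame(variable = character(0), mean0 = numeric(0),
                      se0 = numeric(0), mean1 = numeric(0), se1 = numeric(0),
                      p = numeric(0), p_adjusted = numeric(0),
                      ln_flag = logical(0), applicable = logical(0)))
  d <- cohortData(cohort)
  rows <- lapply(seq_len(nrow(variableSpec)), function(i) {
    vn <- variableSpec$variable[i]
    lnf <- isTRUE(variableSpec$ln_flag[i])
    v <- d[[vn]]
    g <- d[[group]]
    if (is.factor(v)) {
      tab <- table(v, g)
      ct <- chi2Test(tab)
      return(data.frame(variable = vn,
                        mean0 = mean(v[g == FALSE] == levels(v)[2], na.rm = TRUE),
                        se0 = NA_real_,
                        mean1 = mean(v[g == TRUE] == levels(v)[2], na.rm = TRUE),
                        se1 = NA_real_, p = ct$p, p_adjusted = NA_real_,
                        ln_flag = FALSE, applicable = TRUE,
                        stringsAsFactors = FALSE))
    }
    av <- if (lnf) log(ifelse(v > 0, v, NA)) else v
    ok <- !is.na(av) & !is.na(g)
    tt <- ttestIndependent(av[ok], g[ok])
    sem <- function(x) stats::sd(x) / sqrt(length(x))
    analysisCol <- if (lnf) paste0("ln_", vn) else vn
    adj <- if (analysisCol %in% names(d))
      adjustedCompare(cohort, analysisCol, group, covars)
    else {
      tmp <- d; tmp[[analysisCol]] <- av
      adjustedCompare(methods::new("Cohort", data = tmp,
                                   missingLog = numeric(0)),
                      analysisCol, group, covars)
    }
    data.frame(variable = vn,
               mean0 = mean(v[ok & g == FALSE]), se0 = sem(v[ok & g == FALSE]),
               mean1 = mean(v[ok & g == TRUE]), se1 = sem(v[ok & g == TRUE]),
               p = tt$p, p_adjusted = adj$p, ln_flag = lnf,
               applicable = adj$applicable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
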
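#' First-stage instrument strength
#'
#' Fits the first-stage linear model ln_tg ~ dosage + covariates on complete
#' cases and returns the instrument coefficient with its weak-instrument
#' statistics. For a single instrument parameter the partial F statistic
#' equals t^2, and the partial R-squared is t^2 / (t^2 + df) with df the
#' residual degrees of freedom of the model (n - #covariates - 2, counting
#' the intercept). With no covariates the same formulae apply with
#' df = n - 2.
#'
#' @param dosage numeric dosage (or score) vector aligned to the cohort rows.
#' @param cohort Cohort with an \code{ln_tg} column.
#' @param covars covariate names (default c("age", "sex", "bmi"); use
#'   character(0) for the unadjusted model).
#' @param exposure exposure column (default "ln_tg").
#' @return list(beta, se, t, f, partialR2, nUsed, df).
#' @export
instrumentStrength <- function(dosage, cohort, covars = c("age", "sex", "bmi"),
                               exposure = "ln_tg") {
  d <- cohortData(cohort)
  rows <- completeRows(d, c(exposure, covars), dosage)
  if (length(rows) < length(covars) + 3)
    stop("too few complete cases for the first-stage model")
  dd <- d[rows, , drop = FALSE]
  X <- designMatrix(dd, covars, focal = list(dosage = dosage[rows]))
  fit <- olsFit(X, dd[[exposure]])
  t <- unname(fit$statistic["dosage"])
  list(beta = unname(fit$coefficients["dosage"]), se = unname(fit$se["dosage"]),
       t = t, f = t^2, partialR2 = t^2 / (t^2 + fit$df_residual),
       nUsed = fit$n, df = fit$df_residual)
}

#' Partial R-squared from a partial F statistic
#'
#' For a single instrument parameter, partial R^2 = F / (F + df); the
#' arithmetic used to report instrument strength alongside F.
#'
#' @param f partial F statistic (= t^2 for one parameter).
#' @param df residual degrees of freedom of the first-stage model.
#' @return partial R-squared in [0, 1).
#' @export
partialR2FromF <- function(f, df) f / (f + df)

auditRow <- function(id, check, statistic, p, pass, reason = "") {
  data.frame(id = id, check = check, statistic = statistic, p = p,
             pass = pass, reason = reason, stringsAsFactors = FALSE)
}

#' Instrument independence from major covariates
#'
#' Regresses each covariate on the candidate dosage (logistic for sex, linear
#' otherwise); a candidate fails when any covariate association has p below
#' alpha, since association with a confounder-relevant covariate violates the
#' IV independence assumption.
#'
#' @param dosage candidate dosage vector aligned to cohort rows.
#' @param cohort Cohort.
#' @param covars covariates to screen (default age, sex, BMI).
#' @param alpha screen level (default 0.05).
#' @param id candidate id used in the audit rows.
#' @return data.frame of audit rows, one per covariate.
#' @export
checkCovariateIndependence <- function(dosage, cohort,
                                       covars = c("age", "sex", "bmi"),
                                       alpha = 0.05, id = "candidate") {
  d <- cohortData(cohort)
  rows <- completeRows(d, covars, dosage)
  out <- list()
  for (cv in covars) {
    dd <- d[rows, , drop = FALSE]
    if (stats::var(dosage[rows]) == 0) {
      out[[cv]] <- auditRow(id, paste0("independence_", cv), NA, NA, FALSE,
                            "degenerate")
      next
    }
    X <- cbind(`(Intercept)` = 1, dosage = dosage[rows])
    if (cv == "sex") {
      fit <- logisticFit(X, as.numeric(dd$sex == "female"))
    } else {
      fit <- olsFit(X, dd[[cv]])
    }
    p <- unname(fit$p["dosage"])
    out[[cv]] <- auditRow(id, paste0("independence_", cv),
                          unname(fit$statistic["dosage"]), p, p >= alpha,
                          if (p < alpha) "covariate_dependent" else "")
  }
  do.call(rbind, out)
}

#' Screen for a direct instrument-outcome association
#'
#' Covariate-adjusted logistic regression of hypertension on the candidate
#' dosage. The candidate fails when the dosage coefficient is significant;
#' additionally, a significant association whose sign is opposite to the
#' TG-increasing orientation is labeled "direction_inconsistent" — the
#' pattern that excludes an exposure-increasing allele that lowers outcome
#' odds. Note this screen also rejects genuinely valid instruments when the
#' causal effect is strong enough to be visible per allele; that conservatism
#' is by design.
#'
#' @param dosage oriented candidate dosage (first-stage beta > 0).
#' @param cohort Cohort with the \code{htn} outcome.
#' @param covars adjustment covariates (default age, sex, BMI).
#' @param alpha screen level (default 0.05).
#' @param id candidate id for the audit row.
#' @return single audit row.
#' @export
checkOutcomeDirect <- function(dosage, cohort, covars = c("age", "sex", "bmi"),
                               alpha = 0.05, id = "candidate") {
  d <- cohortData(cohort)
  rows <- completeRows(d, c("htn", covars), dosage)
  dd <- d[rows, , drop = FALSE]
  if (stats::var(dosage[rows]) == 0)
    return(auditRow(id, "outcome_direct", NA, NA, FALSE, "degenerate"))
  X <- designMatrix(dd, covars, focal = list(dosage = dosage[rows]))
  fit <- tryCatch(logisticFit(X, as.numeric(dd$htn)), error = function(e) NULL)
  if (is.null(fit))
    return(auditRow(id, "outcome_direct", NA, NA, FALSE, "unstable"))
  p <- unname(fit$p["dosage"])
  b <- unname(fit$coefficients["dosage"])
  reason <- if (p < alpha && b < 0) "direction_inconsistent"
            else if (p < alpha) "direct_association" else ""
  auditRow(id, "outcome_direct", unname(fit$statistic["dosage"]), p,
           p >= alpha, reason)
}

#' Negative-control regressions of instruments on other biomarkers
#'
#' Covariate-adjusted linear regressions of each listed biomarker on each
#' retained instrument. Nominal p-values without multiplicity correction;
#' the table is reporting-only and is never used for instrument selection.
#'
#' @param instrumentSet InstrumentSet.
#' @param genotypes GenotypeMatrix.
#' @param cohort Cohort.
#' @param biomarkers character vector of cohort column names.
#' @param covars adjustment covariates.
#' @return data.frame(instrument, biomarker, beta, se, p).
#' @export
negativeControlScan <- function(instrumentSet, genotypes, cohort, biomarkers,
                                covars = c("age", "sex", "bmi")) {
  iv <- instrumentTable(instrumentSet)
  if (!nrow(iv) || !length(biomarkers))
    return(data.frame(instrument = character(0), biomarker = character(0),
                      beta = numeric(0), se = numeric(0), p = numeric(0)))
  d <- cohortData(cohort)
  out <- list()
  for (i in seq_len(nrow(iv))) {
    dose <- orientedDosage(genotypes, iv$id[i], iv$flipped[i])
    for (bm in biomarkers) {
      rows <- completeRows(d, c(bm, covars), dose)
      dd <- d[rows, , drop = FALSE]
      X <- designMatrix(dd, covars, focal = list(dosage = dose[rows]))
      fit <- olsFit(X, dd[[bm]])
      out[[paste(iv$id[i], bm)]] <- data.frame(
        instrument = iv$id[i], biomarker = bm,
        beta = unname(fit$coefficients["dosage"]),
        se = unname(fit$se["dosage"]), p = unname(fit$p["dosage"]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# Dosage of a variant, flipped to the oriented (exposure-increasing) allele
# when the screening stage flipped it.
orientedDosage <- function(genotypes, id, flipped) {
  j <- match(id, variantInfo(genotypes)$id)
  if (is.na(j)) stop("variant absent from genotype matrix: ", id)
  dose <- dosages(genotypes)[, j]
  if (isTRUE(flipped)) 2 - dose else dose
}

flipAllele <- function(vrow) {
  # after flipping, the counted allele becomes the other allele of the pair
  if (!is.na(vrow$ref) && vrow$counted_allele == vrow$alt) vrow$ref
  else if (!is.na(vrow$alt) && vrow$counted_allele == vrow$ref) vrow$alt
  else paste0("not_", vrow$counted_allele)
}

#' Prespecified instrument screening
#'
#' Applies, to every candidate, the full prespecified instrument checklist:
#' orientation of the counted allele so the first-stage beta is positive,
#' instrument strength (partial F > fMin), independence from major covariates,
#' and absence of a direct covariate-adjusted association with the outcome.
#' Candidates failing any check are excluded with a machine-readable reason;
#' the audit trail covers every candidate and every check.
#'
#' @param genotypes GenotypeMatrix aligned with the cohort.
#' @param cohort Cohort with ln_tg and htn.
#' @param candidates character vector of candidate variant ids (typically
#'   \code{\link{suggestiveHits}} output).
#' @param covars covariates of the weighting first stage (default age, sex,
#'   BMI).
#' @param fMin weak-instrument bar (default 10).
#' @param alpha screening level for the independence and direct-association
#'   checks (default 0.05).
#' @return an \code{\linkS4class{InstrumentSet}}; errors with "no valid
#'   instruments" if nothing survives.
#' @export
selectInstruments <- function(genotypes, cohort, candidates,
                              covars = c("age", "sex", "bmi"),
                              fMin = 10, alpha = 0.05) {
  if (!length(candidates)) stop("no valid instruments: empty candidate list")
  v <- variantInfo(genotypes)
  audit <- list()
  kept <- list()

  for (id in candidates) {
    j <- match(id, v$id)
    if (is.na(j)) stop("candidate absent from genotype matrix: ", id)
    dose <- dosages(genotypes)[, j]
    rows_ok <- !is.na(dose)
    if (sum(rows_ok) < 10 || stats::var(dose[rows_ok]) == 0) {
      audit[[paste(id, "degenerate")]] <-
        auditRow(id, "strength", NA, NA, FALSE, "degenerate")
      next
    }

    st <- instrumentStrength(dose, cohort, covars)
    flipped <- st$beta < 0
    counted <- v$counted_allele[j]
    if (flipped) {
      dose <- 2 - dose
      counted <- flipAllele(v[j, ])
      st <- instrumentStrength(dose, cohort, covars)
    }

    aStrength <- auditRow(id, "strength", st$f, NA, st$f > fMin,
                          if (st$f <= fMin) "weak" else "")
    aIndep <- checkCovariateIndependence(dose, cohort, covars, alpha, id = id)
    aDirect <- checkOutcomeDirect(dose, cohort, covars, alpha, id = id)
    audit[[id]] <- rbind(aStrength, aIndep, aDirect)

    if (all(c(aStrength$pass, aIndep$pass, aDirect$pass))) {
      kept[[id]] <- data.frame(
        id = id, counted_allele = counted, flipped = flipped,
        weight = st$beta, beta = st$beta, se = st$se, f_stat = st$f,
        partial_r2 = st$partialR2, n_used = st$nUsed,
        sensitivity_only = FALSE, stringsAsFactors = FALSE)
    }
  }

  auditDf <- do.call(rbind, audit)
  rownames(auditDf) <- NULL
  if (!length(kept))
    stop("no valid instruments: all ", length(candidates),
         " candidate(s) failed screening")
  vars <- do.call(rbind, kept)
  rownames(vars) <- NULL
  methods::new("InstrumentSet", variants = vars, audit = auditDf,
               covariateSet = covars)
}

#' Expanded (sensitivity-only) instrument set
#'
#' Adds one extra TG-associated variant to an instrument set regardless of
#' the direct-association screen — a sensitivity analysis for instrument
#' choice, flagged as such in the audit. The extra variant must still clear
#' the strength bar; near-perfect collinearity with an existing instrument is
#' flagged.
#'
#' @param genotypes GenotypeMatrix.
#' @param cohort Cohort.
#' @param instrumentSet primary InstrumentSet.
#' @param extraId id of the additional variant.
#' @param fMin strength bar for the extra variant (default 10).
#' @return a new InstrumentSet including the extra variant with
#'   \code{sensitivity_only = TRUE}.
#' @export
expandedGrs <- function(genotypes, cohort, instrumentSet, extraId, fMin = 10) {
  v <- variantInfo(genotypes)
  j <- match(extraId, v$id)
  if (is.na(j)) stop("variant absent from genotype matrix: ", extraId)
  covars <- instrumentSet@covariateSet
  dose <- dosages(genotypes)[, j]
  st <- instrumentStrength(dose, cohort, covars)
  flipped <- st$beta < 0
  counted <- v$counted_allele[j]
  if (flipped) {
    dose <- 2 - dose
    counted <- flipAllele(v[j, ])
    st <- instrumentStrength(dose, cohort, covars)
  }
  if (st$f <= fMin)
    stop("extra variant ", extraId, " fails the strength rule (F = ",
         round(st$f, 2), ")")

  iv <- instrumentTable(instrumentSet)
  audit <- auditTrail(instrumentSet)
  collinear <- FALSE
  for (i in seq_len(nrow(iv))) {
    other <- orientedDosage(genotypes, iv$id[i], iv$flipped[i])
    r <- suppressWarnings(stats::cor(dose, other, use = "pairwise.complete.obs"))
    if (!is.na(r) && abs(r) > 0.95) collinear <- TRUE
  }
  if (collinear)
    warning("extra variant ", extraId,
            " is nearly collinear with an existing instrument")
  audit <- rbind(audit,
                 auditRow(extraId, "strength", st$f, NA, TRUE, ""),
                 auditRow(extraId, "sensitivity_inclusion", NA, NA, TRUE,
                          if (collinear) "collinear;bypasses_direct_check"
                          else "bypasses_direct_check"))
  extra <- data.frame(id = extraId, counted_allele = counted, flipped = flipped,
                      weight = st$beta, beta = st$beta, se = st$se,
                      f_stat = st$f, partial_r2 = st$partialR2,
                      n_used = st$nUsed, sensitivity_only = TRUE,
                      stringsAsFactors = FALSE)
  methods::new("InstrumentSet", variants = rbind(iv, extra), audit = audit,
               covariateSet = covars)
}
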
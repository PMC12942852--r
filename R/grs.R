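#' Weighted genetic risk score
#'
#' score_i = sum_j weight_j x dosage_ij over the instruments, on the oriented
#' (exposure-increasing) allele counts. Individuals missing any instrument
#' genotype are absent from the score (complete-case).
#'
#' @param genotypes GenotypeMatrix.
#' @param instrumentSet InstrumentSet (weights are the first-stage betas).
#' @param includeSensitivity include sensitivity-only variants (expanded
#'   score)? Default FALSE.
#' @return a \code{\linkS4class{GrsVector}} with in-sample weight provenance.
#' @export
buildGrs <- function(genotypes, instrumentSet, includeSensitivity = FALSE) {
  iv <- instrumentTable(instrumentSet)
  if (!includeSensitivity) iv <- iv[!iv$sensitivity_only, , drop = FALSE]
  if (!nrow(iv)) stop("instrument set is empty")
  doseMat <- sapply(seq_len(nrow(iv)), function(i)
    orientedDosage(genotypes, iv$id[i], iv$flipped[i]))
  doseMat <- matrix(doseMat, ncol = nrow(iv),
                    dimnames = list(sampleIds(genotypes), iv$id))
  complete <- rowSums(is.na(doseMat)) == 0
  score <- drop(doseMat[complete, , drop = FALSE] %*% iv$weight)
  names(score) <- rownames(doseMat)[complete]
  methods::new("GrsVector", score = score, foldId = integer(0),
               weightProvenance = "in-sample")
}

#' K-fold cross-fitted genetic risk score
#'
#' Outcome-stratified random folds; for each fold k the per-SNP first-stage
#' weights (and allele orientation) are estimated on all other folds, and
#' scores are computed for fold k only. Removes the in-sample optimism of
#' weights estimated and applied on the same individuals.
#'
#' @param genotypes GenotypeMatrix aligned with the cohort.
#' @param cohort Cohort with ln_tg and htn.
#' @param candidates character vector of instrument variant ids.
#' @param K number of folds (default 10); requires N >= 2K.
#' @param seed RNG seed for fold assignment.
#' @param covars covariates of the weighting first stage.
#' @return a \code{\linkS4class{GrsVector}} with out-of-fold provenance and
#'   per-individual fold ids.
#' @export
crossfitGrs <- function(genotypes, cohort, candidates, K = 10, seed = 1,
                        covars = c("age", "sex", "bmi")) {
  if (K < 2) stop("K must be at least 2")
  d <- cohortData(cohort)
  v <- variantInfo(genotypes)
  j <- match(candidates, v$id)
  if (anyNA(j)) stop("candidate(s) absent from genotype matrix: ",
                     paste(candidates[is.na(j)], collapse = ", "))
  doseMat <- dosages(genotypes)[, j, drop = FALSE]

  rows <- completeRows(d, c("ln_tg", "htn", covars))
  rows <- rows[rowSums(is.na(doseMat[rows, , drop = FALSE])) == 0]
  n <- length(rows)
  if (n < 2 * K) stop("cohort too small for ", K, "-fold cross-fitting")

  # outcome-stratified fold assignment
  fold <- integer(n)
  y <- d$htn[rows]
  fold <- withSeed(seed, {
    f <- integer(n)
    for (lvl in c(TRUE, FALSE)) {
      idx <- which(y == lvl)
      f[idx] <- sample(rep(seq_len(K), length.out = length(idx)))
    }
    f
  })

  score <- rep(NA_real_, n)
  for (k in seq_len(K)) {
    test <- which(fold == k)
    train <- which(fold != k)
    if (length(train) < length(covars) + 3)
      stop("fold ", k, " leaves too few rows to fit the first stage")
    trainCohort <- methods::new("Cohort",
                                data = d[rows[train], , drop = FALSE],
                                missingLog = numeric(0))
    w <- numeric(ncol(doseMat))
    flip <- logical(ncol(doseMat))
    for (m in seq_len(ncol(doseMat))) {
      st <- instrumentStrength(doseMat[rows[train], m], trainCohort, covars)
      flip[m] <- st$beta < 0
      w[m] <- abs(st$beta)
    }
    dm <- doseMat[rows[test], , drop = FALSE]
    for (m in which(flip)) dm[, m] <- 2 - dm[, m]
    score[test] <- drop(dm %*% w)
  }
  names(score) <- d$sample_id[rows]
  foldId <- fold
  names(foldId) <- names(score)
  methods::new("GrsVector", score = score, foldId = foldId,
               weightProvenance = "out-of-fold")
}

#' Fold-wise score-exposure association
#'
#' For a cross-fitted score, regresses the exposure on the score plus
#' covariates separately within each held-out fold. Because every fold's
#' weights were estimated on the other folds, the within-fold test is an
#' ordinary fixed-design regression and its p-value is exactly calibrated;
#' pooling individuals across folds instead reintroduces a correlation
#' between the evaluation data and the weight noise and inflates the pooled
#' test under the null.
#'
#' @param cohort Cohort with the exposure column.
#' @param grs a cross-fitted \code{\linkS4class{GrsVector}} (must carry fold
#'   ids).
#' @param covars covariate names.
#' @param exposure exposure column (default "ln_tg").
#' @return data.frame(fold, n, estimate, se, t, p).
#' @export
foldwiseAssociation <- function(cohort, grs, covars = c("age", "sex", "bmi"),
                                exposure = "ln_tg") {
  if (!length(grs@foldId)) stop("score has no fold assignment; use crossfitGrs()")
  d <- cohortData(cohort)
  s <- scoreVector(grs)
  rows <- match(names(s), d$sample_id)
  out <- lapply(sort(unique(grs@foldId)), function(k) {
    idx <- which(grs@foldId == k)
    dd <- d[rows[idx], , drop = FALSE]
    X <- designMatrix(dd, covars, focal = list(score = s[idx]))
    fit <- olsFit(X, dd[[exposure]])
    data.frame(fold = k, n = fit$n,
               estimate = unname(fit$coefficients["score"]),
               se = unname(fit$se["score"]),
               t = unname(fit$statistic["score"]),
               p = unname(fit$p["score"]))
  })
  do.call(rbind, out)
}
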
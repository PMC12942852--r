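#' Additive per-SNP exposure scan
#'
#' For every variant, fits the linear model exposure ~ dosage + covariates on
#' the complete cases for that variant (the discovery scan adjusts for age
#' and sex; the covariate set is explicit, never hard-coded). Constant dosage
#' columns yield flagged undefined statistics rather than being dropped
#' silently.
#'
#' @param genotypes GenotypeMatrix (rows aligned with the cohort).
#' @param cohort Cohort containing the exposure and covariates.
#' @param exposure exposure column name (default "ln_tg").
#' @param covars covariate names (default c("age", "sex")).
#' @return data.frame of per-variant statistics: id, chrom, pos, n_used,
#'   beta, se, t, p, maf, hwe_p, degenerate.
#' @export
additiveScan <- function(genotypes, cohort, exposure = "ln_tg",
                         covars = c("age", "sex")) {
  d <- cohortData(cohort)
  if (!exposure %in% names(d)) stop("cohort lacks exposure column: ", exposure)
  g <- dosages(genotypes)
  if (!identical(rownames(g), d$sample_id))
    stop("genotypes and cohort are not aligned; call alignCohort() first")
  v <- variantInfo(genotypes)

  base_ok <- completeRows(d, c(exposure, setdiff(covars, "sex")))
  base_ok <- intersect(base_ok, which(!is.na(d$sex) | !"sex" %in% covars))

  res <- lapply(seq_len(ncol(g)), function(j) {
    dose <- g[, j]
    rows <- intersect(base_ok, which(!is.na(dose)))
    nU <- length(rows)
    maf <- if (nU) minorAlleleFreq(dose[rows]) else NA_real_
    hwe <- if (nU) hweColumnP(dose[rows]) else NA_real_
    if (nU < length(covars) + 3 || stats::var(dose[rows]) == 0)
      return(data.frame(id = v$id[j], chrom = v$chrom[j], pos = v$pos[j],
                        n_used = nU, beta = NA_real_, se = NA_real_,
                        t = NA_real_, p = NA_real_, maf = maf, hwe_p = hwe,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    dd <- d[rows, , drop = FALSE]
    X <- designMatrix(dd, covars, focal = list(dosage = dose[rows]))
    fit <- olsFit(X, dd[[exposure]])
    data.frame(id = v$id[j], chrom = v$chrom[j], pos = v$pos[j], n_used = nU,
               beta = fit$coefficients["dosage"], se = fit$se["dosage"],
               t = fit$statistic["dosage"], p = fit$p["dosage"],
               maf = maf, hwe_p = hwe, degenerate = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Candidate instruments at the suggestive threshold
#'
#' Variant ids whose scan p-value falls below the genome-wide suggestive
#' threshold used for exploratory instrument discovery, sorted by ascending
#' p.
#'
#' @param stats scan results from \code{\link{additiveScan}}.
#' @param alpha threshold (default 1e-5).
#' @return character vector of variant ids.
#' @export
suggestiveHits <- function(stats, alpha = 1e-5) {
  if (!nrow(stats)) return(character(0))
  hit <- !is.na(stats$p) & stats$p < alpha
  stats$id[hit][order(stats$p[hit])]
}
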
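#' Sample and marker call-rate filters
#'
#' Samples with individual call rate below \code{sampleMin} are removed first,
#' then markers with call rate below \code{markerMin} (computed on the
#' remaining samples). This order matches common genotype-QC practice.
#'
#' @param genotypes GenotypeMatrix.
#' @param sampleMin minimum per-sample call rate (default 0.90).
#' @param markerMin minimum per-marker call rate (default 0.95).
#' @return list(genotypes, report) where report counts removals per stage.
#' @export
callRateFilter <- function(genotypes, sampleMin = 0.90, markerMin = 0.95) {
  d <- dosages(genotypes)
  sampleRate <- rowMeans(!is.na(d))
  keepS <- sampleRate >= sampleMin
  d2 <- d[keepS, , drop = FALSE]
  markerRate <- colMeans(!is.na(d2))
  keepM <- markerRate >= markerMin
  out <- methods::new("GenotypeMatrix",
                      dosages = d2[, keepM, drop = FALSE],
                      variants = variantInfo(genotypes)[keepM, , drop = FALSE])
  report <- list(
    samples_in = nrow(d), samples_removed_callrate = sum(!keepS),
    markers_in = ncol(d), markers_removed_callrate = sum(!keepM),
    removed_samples = rownames(d)[!keepS],
    removed_markers = colnames(d)[!keepM],
    thresholds = list(sample_call = sampleMin, marker_call = markerMin))
  list(genotypes = out, report = report)
}

#' Minor allele frequency of a dosage column
#'
#' f = (sum of dosages) / (2 x non-missing count); MAF = min(f, 1 - f).
#'
#' @param dosage numeric vector of 0/1/2/NA.
#' @return MAF in [0, 0.5].
#' @export
minorAlleleFreq <- function(dosage) {
  ok <- !is.na(dosage)
  if (!any(ok)) stop("all-missing dosage column")
  f <- sum(dosage[ok]) / (2 * sum(ok))
  min(f, 1 - f)
}

# Counted-allele frequency (not folded to minor).
countedFreq <- function(dosage) {
  ok <- !is.na(dosage)
  sum(dosage[ok]) / (2 * sum(ok))
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test: the p-value is the sum of probabilities, under the
#' HWE null conditional on the observed allele counts, of all heterozygote
#' counts whose probability does not exceed that of the observed count.
#' Probabilities follow the hypergeometric-type recurrence
#' P(nAB + 2) / P(nAB) = 4 nA' nB' / ((nAB + 2)(nAB + 1)) on the heterozygote
#' ladder with matching parity.
#'
#' @param nAA,nAa,naa genotype counts (AA homozygote, heterozygote, aa
#'   homozygote).
#' @return exact p-value in (0, 1].
#' @export
hweExactP <- function(nAA, nAa, naa) {
  if (any(c(nAA, nAa, naa) < 0)) stop("genotype counts must be nonnegative")
  n <- nAA + nAa + naa
  if (n == 0) stop("no genotypes")
  nA <- 2 * nAA + nAa
  na <- 2 * naa + nAa
  rare <- min(nA, na)
  if (rare == 0) return(1)  # monomorphic

  # heterozygote counts share the parity of the rare-allele count; work on the
  # log scale so long ladders (large n) cannot overflow before normalization
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- numeric(length(hets))
  if (length(hets) > 1) {
    for (i in 2:length(hets)) {
      h <- hets[i - 1]
      rareHom <- (rare - h) / 2
      commonHom <- n - h - rareHom
      # log P(h+2) - log P(h) = log(4 * rareHom * commonHom / ((h+2)(h+1)))
      lp[i] <- lp[i - 1] + log(4) + log(rareHom) + log(commonHom) -
        log(h + 2) - log(h + 1)
    }
  }
  probs <- exp(lp - max(lp))
  probs <- probs / sum(probs)
  pObs <- probs[match(nAa, hets)]
  if (is.na(pObs)) stop("heterozygote count inconsistent with allele counts")
  min(1, sum(probs[probs <= pObs * (1 + 1e-12)]))
}

# chi-square HWE test (1 df), available behind qcPipeline(hweMethod="chisq")
hweChisqP <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  p <- (2 * nAA + nAa) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(e == 0)) return(1)
  stat <- sum((c(nAA, nAa, naa) - e)^2 / e)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

hweColumnP <- function(dosage, method = "exact") {
  d <- dosage[!is.na(dosage)]
  counts <- c(sum(d == 2), sum(d == 1), sum(d == 0))
  if (method == "exact") hweExactP(counts[1], counts[2], counts[3])
  else hweChisqP(counts[1], counts[2], counts[3])
}

#' Genotype QC pipeline
#'
#' Applies, in order: sample call-rate filter, marker call-rate filter, MAF
#' filter, exact HWE filter. LD pruning is deliberately not part of this
#' pipeline; it is applied only during instrument selection (see
#' \code{\link{ldPrune}}).
#'
#' @param genotypes GenotypeMatrix.
#' @param sampleCall,markerCall,mafMin,hwePmin thresholds (defaults 0.90,
#'   0.95, 0.01, 0.001).
#' @param hweMethod "exact" (default) or "chisq".
#' @return list(genotypes, report); the report counts removals per filter and
#'   satisfies removed + retained = input at each stage.
#' @export
qcPipeline <- function(genotypes, sampleCall = 0.90, markerCall = 0.95,
                       mafMin = 0.01, hwePmin = 0.001, hweMethod = "exact") {
  cr <- callRateFilter(genotypes, sampleCall, markerCall)
  g <- cr$genotypes
  d <- dosages(g)

  mafs <- apply(d, 2, function(col) if (all(is.na(col))) 0 else minorAlleleFreq(col))
  keepMaf <- mafs >= mafMin
  d <- d[, keepMaf, drop = FALSE]

  hwep <- apply(d, 2, hweColumnP, method = hweMethod)
  keepHwe <- hwep >= hwePmin
  out <- methods::new("GenotypeMatrix",
                      dosages = d[, keepHwe, drop = FALSE],
                      variants = variantInfo(g)[keepMaf, , drop = FALSE][keepHwe, , drop = FALSE])

  report <- list(
    samples_in = cr$report$samples_in,
    samples_removed_callrate = cr$report$samples_removed_callrate,
    samples_retained = nrow(dosages(out)),
    markers_in = cr$report$markers_in,
    markers_removed_callrate = cr$report$markers_removed_callrate,
    markers_removed_maf = sum(!keepMaf),
    markers_removed_hwe = sum(!keepHwe),
    markers_retained = ncol(dosages(out)),
    removed = list(callrate = cr$report$removed_markers,
                   maf = colnames(dosages(g))[!keepMaf],
                   hwe = colnames(d)[!keepHwe]),
    thresholds = list(sample_call = sampleCall, marker_call = markerCall,
                      maf = mafMin, hwe_p = hwePmin, hwe_method = hweMethod))
  list(genotypes = out, report = report)
}

#' Windowed LD pruning on pairwise dosage correlation
#'
#' Greedy pruning in the style of PLINK's indep-pairwise: per chromosome, in a
#' sliding window of \code{window} variants advanced by \code{step}, every
#' pair of retained variants with squared Pearson correlation above
#' \code{r2Max} loses its later member (later by position, ties by id) — note
#' this equals keeping the first-seen variant. Input must be sorted by
#' (chromosome, position).
#'
#' @param genotypes GenotypeMatrix sorted by chromosome and position.
#' @param window window size in variants (default 250).
#' @param step window step in variants (default 50).
#' @param r2Max maximum allowed squared correlation (default 0.5).
#' @return list(genotypes, report).
#' @export
ldPrune <- function(genotypes, window = 250, step = 50, r2Max = 0.5) {
  v <- variantInfo(genotypes)
  d <- dosages(genotypes)
  ord <- order(v$chrom, v$pos, v$id)
  if (!identical(ord, seq_len(nrow(v))))
    stop("variants must be sorted by (chromosome, position) before pruning")

  keep <- rep(TRUE, ncol(d))
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr)
    starts <- seq(1, max(1, length(idx)), by = step)
    for (s in starts) {
      win <- idx[s:min(s + window - 1, length(idx))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      for (a in seq_len(length(win) - 1)) {
        ia <- win[a]
        if (!keep[ia]) next
        for (b in (a + 1):length(win)) {
          ib <- win[b]
          if (!keep[ib]) next
          r <- suppressWarnings(
            stats::cor(d[, ia], d[, ib], use = "pairwise.complete.obs"))
          if (!is.na(r) && r^2 > r2Max) keep[ib] <- FALSE
        }
      }
      if (s + window - 1 >= length(idx)) break
    }
  }
  out <- methods::new("GenotypeMatrix",
                      dosages = d[, keep, drop = FALSE],
                      variants = v[keep, , drop = FALSE])
  report <- list(markers_in = ncol(d), markers_removed_pruning = sum(!keep),
                 removed = colnames(d)[!keep],
                 thresholds = list(window = window, step = step, r2_max = r2Max))
  list(genotypes = out, report = report)
}
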
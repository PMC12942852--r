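# Small programmatic fixtures shared across test files.

# A hand-written cohort of n individuals with deterministic covariates and a
# supplied exposure/outcome, for closed-form checks.
makeCohort <- function(df) {
  if (!"sample_id" %in% names(df))
    df$sample_id <- sprintf("S%03d", seq_len(nrow(df)))
  if ("sex" %in% names(df) && !is.factor(df$sex))
    df$sex <- factor(df$sex, levels = c("male", "female"))
  new("Cohort", data = df, missingLog = numeric(0))
}

# GenotypeMatrix from an explicit dosage matrix (columns = variants).
makeGenotypes <- function(d, chrom = NULL, pos = NULL, counted = NULL) {
  if (is.null(rownames(d))) rownames(d) <- sprintf("S%03d", seq_len(nrow(d)))
  if (is.null(colnames(d))) colnames(d) <- paste0("v", seq_len(ncol(d)))
  m <- ncol(d)
  v <- data.frame(id = colnames(d),
                  chrom = chrom %||% rep("1", m),
                  pos = pos %||% seq_len(m) * 100L,
                  ref = rep("A", m), alt = rep("G", m),
                  counted_allele = counted %||% rep("G", m),
                  stringsAsFactors = FALSE)
  new("GenotypeMatrix", dosages = d * 1.0, variants = v)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expand a 2x2 outcome-by-exposure table (a = exposed cases, b = exposed
# controls, c = unexposed cases, d = unexposed controls) into indicator rows.
expandTable <- function(a, b, c, d) {
  x <- c(rep(1, a + b), rep(0, c + d))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  list(x = x, y = y)
}

# Full-enumeration oracle for the exact HWE test: hypergeometric-type
# probability of each heterozygote count conditional on the allele counts,
# computed directly from log-factorials (independent of the recurrence used
# by the implementation).
hweEnumP <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  rare <- min(nA, 2 * n - nA)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  lp <- vapply(hets, function(h) {
    rHom <- (rare - h) / 2
    cHom <- n - h - rHom
    lfactorial(n) - lfactorial(rHom) - lfactorial(h) - lfactorial(cHom) +
      h * log(2) - (lfactorial(2 * n) - lfactorial(rare) -
                    lfactorial(2 * n - rare))
  }, numeric(1))
  probs <- exp(lp - max(lp))
  probs <- probs / sum(probs)
  pObs <- probs[match(nAa, hets)]
  min(1, sum(probs[probs <= pObs * (1 + 1e-12)]))
}

# A deterministic small cohort + genotypes with a planted instrument effect,
# used by several screening tests.
plantedSim <- function(n = 2000, seed = 7, scenario = "causal", ...) {
  simulateCohort(simulationConfig(scenario, n = n, seed = as.integer(seed),
                                  nNullSnps = 0L, ...))
}
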
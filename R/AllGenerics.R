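#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("cohortData", function(x) standardGeneric("cohortData"))

#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))

#' @export
setGeneric("instrumentTable", function(x) standardGeneric("instrumentTable"))

#' @export
setGeneric("auditTrail", function(x) standardGeneric("auditTrail"))

#' @export
setGeneric("scoreVector", function(x) standardGeneric("scoreVector"))

#' Accessors
#'
#' Accessor methods for the package's data containers.
#'
#' @param x a \code{Cohort}, \code{GenotypeMatrix}, \code{InstrumentSet} or
#'   \code{GrsVector} object.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setMethod("sampleIds", "Cohort", function(x) x@data$sample_id)

#' @rdname accessors
#' @export
setMethod("sampleIds", "GenotypeMatrix", function(x) rownames(x@dosages))

#' @rdname accessors
#' @export
setMethod("cohortData", "Cohort", function(x) x@data)

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosages)

#' @rdname accessors
#' @export
setMethod("variantInfo", "GenotypeMatrix", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("nVariants", "GenotypeMatrix", function(x) ncol(x@dosages))

#' @rdname accessors
#' @export
setMethod("instrumentTable", "InstrumentSet", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("auditTrail", "InstrumentSet", function(x) x@audit)

#' @rdname accessors
#' @export
setMethod("scoreVector", "GrsVector", function(x) x@score)

setMethod("show", "Cohort", function(object) {
  d <- object@data
  cat("Cohort with", nrow(d), "individuals and", ncol(d), "columns\n")
  if ("htn" %in% names(d))
    cat("  hypertension prevalence:",
        sprintf("%.1f%%", 100 * mean(d$htn, na.rm = TRUE)), "\n")
  derived <- grep("^(ln_|homa)", names(d), value = TRUE)
  if (length(derived)) cat("  derived columns:", paste(derived, collapse = ", "), "\n")
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@dosages), "samples x",
      ncol(object@dosages), "variants\n")
  miss <- mean(is.na(object@dosages))
  cat(sprintf("  missingness: %.2f%%\n", 100 * miss))
})

setMethod("show", "InstrumentSet", function(object) {
  v <- object@variants
  cat("InstrumentSet with", nrow(v), "instrument(s)",
      sprintf("(weights adjusted for %s)\n", paste(object@covariateSet, collapse = "+")))
  if (nrow(v))
    print(v[, c("id", "counted_allele", "weight", "f_stat", "partial_r2", "n_used")],
          row.names = FALSE, digits = 3)
  cat("  audit records:", nrow(object@audit), "\n")
})

setMethod("show", "GrsVector", function(object) {
  cat("GrsVector:", length(object@score), "individuals,",
      object@weightProvenance, "weights\n")
})

setMethod("show", "MrEstimate", function(object) {
  scale <- if (is.na(object@orValue)) "slope" else "OR"
  val <- if (is.na(object@orValue)) object@estimate else object@orValue
  cat(sprintf("%s [%s, %s] %s = %.2f (95%% CI %.2f-%.2f), p = %.3g, n = %d\n",
              object@method, object@label, object@model, scale, val,
              object@ciLow, object@ciHigh, object@p, object@n))
  if (!is.na(object@firstStageF))
    cat(sprintf("  first stage: F = %.1f, partial R2 = %.3f\n",
                object@firstStageF, object@firstStageR2))
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf("SimulationConfig [%s]: n = %d, %d instrument(s), %d null SNPs, seed = %d\n",
              object@scenario, object@n, length(object@instrumentMafs),
              object@nNullSnps, object@seed))
  cat(sprintf("  thetaTG = %.3f, gammaU = %.2f, thetaU = %.2f, target prevalence = %.3f\n",
              object@thetaTG, object@gammaU, object@thetaU, object@targetPrevalence))
})
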
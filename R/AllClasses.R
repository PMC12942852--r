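#' Cohort: per-individual phenotypes, covariates and derived variables
#'
#' Container for the analysis-facing phenotype table: identifiers, age, sex
#' (factor with male as the reference level), BMI, blood pressure, medication
#' use, biomarkers, derived columns (natural-log transforms, HOMA-IR) and the
#' hypertension indicator. Sample identifiers must be unique.
#'
#' @slot data data.frame with one row per individual; must contain a
#'   \code{sample_id} column of unique character identifiers. The sex column,
#'   when present, is a factor with levels \code{c("male", "female")} so that
#'   model indicators code 1 = female.
#' @slot missingLog named numeric; per-column counts of values set to missing
#'   during derivation (e.g. nonpositive inputs to a log transform).
#' @export
setClass("Cohort",
  representation(data = "data.frame", missingLog = "numeric"),
  prototype(data = data.frame(), missingLog = numeric(0))
)

setValidity("Cohort", function(object) {
  d <- object@data
  if (nrow(d) == 0) return(TRUE)
  if (!"sample_id" %in% names(d)) return("data must contain a sample_id column")
  if (anyDuplicated(d$sample_id)) {
    dup <- unique(d$sample_id[duplicated(d$sample_id)])
    return(paste0("duplicate sample_id: ", paste(utils::head(dup, 5), collapse = ", ")))
  }
  if ("sex" %in% names(d) && is.factor(d$sex) &&
      !identical(levels(d$sex), c("male", "female")))
    return("sex must be a factor with levels c('male','female') (male = reference)")
  TRUE
})

#' GenotypeMatrix: additive dosages with variant metadata
#'
#' N x M matrix of counted-allele dosages in \{0, 1, 2\} with \code{NA} as the
#' missing code, plus per-variant metadata. Rows are samples (rownames are
#' sample identifiers), columns are variants in the order of the metadata
#' table.
#'
#' @slot dosages numeric matrix; entries 0/1/2/NA; rownames = sample ids,
#'   colnames = variant ids.
#' @slot variants data.frame with columns \code{id}, \code{chrom}, \code{pos}
#'   (1-based integer), \code{ref}, \code{alt}, \code{counted_allele}.
#' @export
setClass("GenotypeMatrix",
  representation(dosages = "matrix", variants = "data.frame")
)

setValidity("GenotypeMatrix", function(object) {
  d <- object@dosages
  v <- object@variants
  need <- c("id", "chrom", "pos", "ref", "alt", "counted_allele")
  if (!all(need %in% names(v)))
    return(paste0("variants must have columns: ", paste(need, collapse = ", ")))
  if (ncol(d) != nrow(v)) return("ncol(dosages) must equal nrow(variants)")
  if (anyDuplicated(v$id)) return("variant ids must be unique")
  if (is.null(rownames(d)) && nrow(d) > 0) return("dosages must have sample rownames")
  if (nrow(d) > 0 && anyDuplicated(rownames(d))) return("sample ids must be unique")
  if (!identical(colnames(d), as.character(v$id)))
    return("colnames(dosages) must equal variants$id")
  vals <- d[!is.na(d)]
  if (length(vals) && !all(vals %in% c(0, 1, 2)))
    return("non-missing dosages must be 0, 1 or 2")
  TRUE
})

#' InstrumentSet: screened instruments with weights and audit trail
#'
#' The retained instruments (id, counted allele after orientation, first-stage
#' weight and strength statistics) together with a complete audit of every
#' candidate and every prespecified check, retained or not.
#'
#' @slot variants data.frame: id, counted_allele, flipped (orientation applied
#'   to the stored dosage), weight (ln-units per allele, > 0 after
#'   orientation), beta, se, f_stat, partial_r2, n_used, sensitivity_only.
#' @slot audit data.frame: id, check, statistic, p, pass, reason.
#' @slot covariateSet character; covariates of the weighting first stage.
#' @export
setClass("InstrumentSet",
  representation(variants = "data.frame", audit = "data.frame",
                 covariateSet = "character")
)

setValidity("InstrumentSet", function(object) {
  v <- object@variants
  if (nrow(v) && any(!is.na(v$weight) & v$weight <= 0 & !v$sensitivity_only))
    return("retained primary instruments must have positive weight after orientation")
  if (nrow(v) && !all(v$id %in% object@audit$id))
    return("audit must cover every retained instrument")
  TRUE
})

#' GrsVector: per-individual weighted genetic risk score
#'
#' @slot score named numeric; one value per individual with complete genotypes
#'   on every instrument (complete-case).
#' @slot foldId named integer of the same length as score when cross-fitted,
#'   otherwise length 0.
#' @slot weightProvenance "in-sample" or "out-of-fold".
#' @export
setClass("GrsVector",
  representation(score = "numeric", foldId = "integer",
                 weightProvenance = "character")
)

setValidity("GrsVector", function(object) {
  if (any(!is.finite(object@score))) return("scores must be finite")
  if (!object@weightProvenance %in% c("in-sample", "out-of-fold"))
    return("weightProvenance must be 'in-sample' or 'out-of-fold'")
  if (length(object@foldId) && length(object@foldId) != length(object@score))
    return("foldId must be empty or match score length")
  TRUE
})

#' MrEstimate: a method-tagged causal estimate
#'
#' One causal estimate with its scale, Wald interval, first-stage diagnostics
#' and provenance. For 2SPS/2SRI the estimate is a log odds ratio per unit of
#' (genetically predicted) ln exposure; for 2SLS it is a linear-probability
#' slope and \code{orValue} is \code{NA}.
#'
#' @slot method "2SPS", "2SRI" or "2SLS".
#' @slot label instrument label (SNP id, "GRS", "crossfit-GRS", "expanded-GRS",
#'   or "observational" for the conventional arm rows).
#' @slot model "crude" or "adjusted".
#' @slot estimate numeric; log-OR (2SPS/2SRI) or risk-difference slope (2SLS).
#' @slot orValue exp(estimate) where the estimate is a log-OR, else NA.
#' @slot ciLow,ciHigh 95% interval on the reporting scale (OR scale when
#'   orValue is defined, slope scale otherwise).
#' @slot p two-sided p-value.
#' @slot firstStageF,firstStageR2 weak-instrument diagnostics (NA for
#'   observational rows).
#' @slot n complete-case sample size used.
#' @slot covariateSet covariates of the fit.
#' @slot seMethod "wald" or "bootstrap".
#' @slot detail list of internals (residuals, design pieces) consumed by
#'   diagnostic tests; not part of the reporting surface.
#' @export
setClass("MrEstimate",
  representation(method = "character", label = "character", model = "character",
                 estimate = "numeric", orValue = "numeric",
                 ciLow = "numeric", ciHigh = "numeric", p = "numeric",
                 firstStageF = "numeric", firstStageR2 = "numeric",
                 n = "integer", covariateSet = "character",
                 seMethod = "character", detail = "list"),
  prototype(detail = list(), seMethod = "wald")
)

setValidity("MrEstimate", function(object) {
  if (!is.na(object@orValue) && object@seMethod == "wald" &&
      !(object@ciLow < object@orValue && object@orValue < object@ciHigh))
    return("Wald interval must bracket the odds ratio")
  if (!is.na(object@p) && (object@p < 0 || object@p > 1)) return("p must be in [0,1]")
  TRUE
})

#' SimulationConfig: full generative recipe for a synthetic cohort
#'
#' Every parameter of the generator: instrument minor-allele frequencies and
#' per-allele effects on ln(TG), the number of null markers, covariate and
#' confounder effects on exposure and outcome, the causal effect, the target
#' hypertension prevalence, optional direct (pleiotropic) SNP-outcome effects,
#' genotype missingness, the seed and a scenario tag. See
#' \code{\link{simulationConfig}} for defaults and scenario presets.
#'
#' @export
setClass("SimulationConfig",
  representation(
    n = "integer",
    instrumentMafs = "numeric", instrumentBetas = "numeric",
    nNullSnps = "integer", nullMafRange = "numeric",
    gammaU = "numeric", thetaU = "numeric", thetaTG = "numeric",
    gammaAge = "numeric", gammaSex = "numeric", gammaBmi = "numeric",
    thetaAge = "numeric", thetaSex = "numeric", thetaBmi = "numeric",
    alpha0 = "numeric", sigmaEps = "numeric",
    targetPrevalence = "numeric", pleiotropyDelta = "numeric",
    missingRate = "numeric", seed = "integer", scenario = "character"
  )
)

setValidity("SimulationConfig", function(object) {
  if (any(object@instrumentMafs <= 0 | object@instrumentMafs > 0.5))
    return("instrument MAFs must lie in (0, 0.5]")
  if (length(object@instrumentMafs) != length(object@instrumentBetas))
    return("instrumentMafs and instrumentBetas must have equal length")
  if (length(object@pleiotropyDelta) != length(object@instrumentMafs))
    return("pleiotropyDelta must have one entry per instrument")
  if (object@targetPrevalence <= 0 || object@targetPrevalence >= 1)
    return("targetPrevalence must lie in (0, 1)")
  if (object@missingRate < 0 || object@missingRate >= 1)
    return("missingRate must lie in [0, 1)")
  if (!object@scenario %in% c("null", "causal", "confounded_null", "pleiotropic"))
    return("unknown scenario tag")
  if (object@sigmaEps < 0) return("sigmaEps must be nonnegative")
  TRUE
})
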
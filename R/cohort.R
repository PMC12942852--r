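#' Describe the layout of a phenotype file
#'
#' A \code{PhenotypeSpec} maps file columns onto the required cohort fields and
#' declares the sex coding and the missing-value sentinel. Every required field
#' must be mapped exactly once.
#'
#' @param columns named character; names are the cohort fields
#'   (\code{sample_id}, \code{age}, \code{sex}, \code{bmi}, \code{sbp},
#'   \code{dbp}, \code{on_htn_med} plus any biomarker columns), values are the
#'   column names in the file.
#' @param sexCoding named character of length 2 with names \code{male} and
#'   \code{female} giving the codes used in the file; male is always the
#'   reference level.
#' @param missing character sentinel for missing values (default "NA").
#' @return a list of class \code{phenotypeSpec}.
#' @export
phenotypeSpec <- function(columns = c(sample_id = "sample_id", age = "age",
                                      sex = "sex", bmi = "bmi", sbp = "sbp",
                                      dbp = "dbp", on_htn_med = "on_htn_med"),
                          sexCoding = c(male = "male", female = "female"),
                          missing = "NA") {
  required <- c("sample_id", "age", "sex", "bmi", "sbp", "dbp", "on_htn_med")
  absent <- setdiff(required, names(columns))
  if (length(absent))
    stop("phenotype spec must map required columns: ", paste(absent, collapse = ", "))
  if (anyDuplicated(columns))
    stop("each file column may be mapped at most once")
  if (!all(c("male", "female") %in% names(sexCoding)))
    stop("sexCoding must name both 'male' and 'female'")
  structure(list(columns = columns, sexCoding = sexCoding, missing = missing),
            class = "phenotypeSpec")
}

#' Read a delimited phenotype table into a Cohort
#'
#' Reads a TSV/CSV with a header, applies the column mapping of the spec, types
#' the required columns, recodes sex to a factor with male as the reference
#' level, and flags (rather than drops) rows whose required numeric fields do
#' not parse.
#'
#' @param path file path; tab- or comma-delimited, inferred from the extension.
#' @param spec a \code{\link{phenotypeSpec}}.
#' @return a \code{\linkS4class{Cohort}}. Unparseable required fields are
#'   \code{NA} and counted in a \code{parse_failures} attribute on the data.
#' @export
readPhenotypeTable <- function(path, spec = phenotypeSpec()) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           na.strings = spec$missing, stringsAsFactors = FALSE)
  cols <- spec$columns
  absent <- cols[!cols %in% names(raw)]
  if (length(absent))
    stop("missing required column(s) in ", path, ": ", paste(absent, collapse = ", "))

  d <- data.frame(sample_id = as.character(raw[[cols["sample_id"]]]),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$sample_id)) {
    dup <- unique(d$sample_id[duplicated(d$sample_id)])
    stop("duplicate sample_id in ", path, ": ", paste(dup, collapse = ", "))
  }

  numeric_fields <- setdiff(names(cols), c("sample_id", "sex", "on_htn_med"))
  failures <- 0L
  for (f in numeric_fields) {
    v <- raw[[cols[f]]]
    parsed <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & is.na(parsed)
    if (any(bad)) failures <- failures + sum(bad)
    d[[f]] <- parsed
  }

  sx <- raw[[cols["sex"]]]
  sexv <- rep(NA_character_, length(sx))
  sexv[sx == spec$sexCoding["male"]] <- "male"
  sexv[sx == spec$sexCoding["female"]] <- "female"
  unknown <- !is.na(sx) & is.na(sexv)
  if (any(unknown))
    stop("unrecognized sex code(s): ", paste(unique(sx[unknown]), collapse = ", "))
  d$sex <- factor(sexv, levels = c("male", "female"))

  med <- raw[[cols["on_htn_med"]]]
  d$on_htn_med <- as.logical(ifelse(med %in% c("1", "TRUE", "true", "T"), TRUE,
                             ifelse(med %in% c("0", "FALSE", "false", "F"), FALSE, NA)))

  attr(d, "parse_failures") <- failures
  methods::new("Cohort", data = d, missingLog = numeric(0))
}

#' Write a Cohort to a deterministic TSV
#'
#' Fixed column order (sample_id first, then alphabetical), \code{NA} sentinel,
#' full-precision floats via \code{format(..., digits = 17)} so that a write /
#' read round trip is bit-identical for finite values.
#'
#' @param cohort a Cohort.
#' @param path output path.
#' @export
writePhenotypeTable <- function(cohort, path) {
  d <- cohortData(cohort)
  ord <- c("sample_id", sort(setdiff(names(d), "sample_id")))
  d <- d[, ord, drop = FALSE]
  out <- lapply(d, function(v) {
    if (is.numeric(v)) ifelse(is.na(v), "NA", format(v, digits = 17, trim = TRUE, scientific = FALSE))
    else if (is.logical(v)) ifelse(is.na(v), "NA", ifelse(v, "1", "0"))
    else as.character(v)
  })
  utils::write.table(as.data.frame(out, stringsAsFactors = FALSE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an additive dosage table
#'
#' Supports the PLINK \code{.raw} additive dialect (header \code{FID IID PAT
#' MAT SEX PHENOTYPE} followed by one column per variant named
#' \code{<id>_<countedAllele>}) and the package's internal TSV (sample_id
#' column then variant columns with the same naming). The counted allele is
#' parsed from the header suffix; \code{"NA"} becomes the missing code, never
#' zero.
#'
#' @param path dosage file path.
#' @param variantMeta optional path to a sidecar variant-metadata TSV with
#'   columns id, chrom, pos, ref, alt; when absent, chromosome/position are
#'   synthesized (chrom "0", consecutive positions) and ref is unknown.
#' @return a \code{\linkS4class{GenotypeMatrix}}.
#' @export
readDosageTable <- function(path, variantMeta = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(raw) == 1)  # .raw files are space-delimited
    raw <- utils::read.table(path, header = TRUE, sep = "", colClasses = "character",
                             check.names = FALSE, stringsAsFactors = FALSE)
  plink_lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (all(plink_lead %in% names(raw)[1:6])) {
    ids <- raw$IID
    gcols <- setdiff(names(raw), plink_lead)
  } else if ("sample_id" %in% names(raw)) {
    ids <- raw$sample_id
    gcols <- setdiff(names(raw), "sample_id")
  } else stop("unrecognized dosage header: expected PLINK .raw leading columns or sample_id")

  if (anyDuplicated(ids)) stop("duplicate sample identifiers in dosage table")
  m <- regmatches(gcols, regexec("^(.*)_([ACGT0-9]+)$", gcols))
  bad <- vapply(m, length, 0L) != 3
  if (any(bad))
    stop("variant column(s) without a counted-allele suffix: ",
         paste(utils::head(gcols[bad], 5), collapse = ", "))
  vid <- vapply(m, `[`, "", 2)
  counted <- vapply(m, `[`, "", 3)

  d <- matrix(NA_real_, nrow = length(ids), ncol = length(gcols),
              dimnames = list(ids, vid))
  for (j in seq_along(gcols)) {
    v <- raw[[gcols[j]]]
    x <- suppressWarnings(as.numeric(v))
    bad <- !is.na(v) & v != "NA" & (is.na(x) | !x %in% c(0, 1, 2))
    if (any(bad))
      stop("dosage outside {0,1,2,NA} in column ", gcols[j], ": ",
           paste(utils::head(unique(v[bad]), 3), collapse = ", "))
    d[, j] <- x
  }

  if (!is.null(variantMeta)) {
    vm <- utils::read.table(variantMeta, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, colClasses = "character")
    vm$pos <- as.integer(vm$pos)
    vm <- vm[match(vid, vm$id), ]
    if (anyNA(vm$id)) stop("variant metadata missing entries for some dosage columns")
    variants <- data.frame(id = vid, chrom = vm$chrom, pos = vm$pos,
                           ref = vm$ref, alt = vm$alt, counted_allele = counted,
                           stringsAsFactors = FALSE)
  } else {
    variants <- data.frame(id = vid, chrom = "0", pos = seq_along(vid),
                           ref = NA_character_, alt = counted,
                           counted_allele = counted, stringsAsFactors = FALSE)
  }
  methods::new("GenotypeMatrix", dosages = d, variants = variants)
}

#' Write a GenotypeMatrix as internal TSV plus variant-metadata sidecar
#'
#' @param genotypes a GenotypeMatrix.
#' @param path dosage TSV path; the sidecar is written to
#'   \code{paste0(path, ".variants.tsv")}.
#' @export
writeDosageTable <- function(genotypes, path) {
  d <- dosages(genotypes)
  v <- variantInfo(genotypes)
  hdr <- paste0(v$id, "_", v$counted_allele)
  out <- data.frame(sample_id = rownames(d), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(d)))
    out[[hdr[j]]] <- ifelse(is.na(d[, j]), "NA", format(d[, j], trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(v[, c("id", "chrom", "pos", "ref", "alt")],
                     paste0(path, ".variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Classify hypertension from blood pressure and medication use
#'
#' Hypertension is defined as systolic blood pressure of at least 140 mmHg, or
#' diastolic blood pressure of at least 90 mmHg, or current use of
#' antihypertensive medication. Any missing input yields a missing
#' classification (the row is excluded downstream rather than guessed).
#'
#' @param sbp,dbp systolic / diastolic pressure, mmHg.
#' @param onMed logical; current antihypertensive medication use.
#' @return logical vector, NA where any input is missing.
#' @export
classifyHypertension <- function(sbp, dbp, onMed) {
  out <- sbp >= 140 | dbp >= 90 | onMed
  out[is.na(sbp) | is.na(dbp) | is.na(onMed)] <- NA
  out
}

#' Add a natural-log transformed column to a Cohort
#'
#' Creates \code{ln_<column>}. Nonpositive source values cannot be
#' log-transformed; they become missing and are counted in the cohort's
#' missing-value log.
#'
#' @param cohort a Cohort.
#' @param column name of an existing positive-valued column.
#' @return the Cohort with the new column.
#' @export
deriveLn <- function(cohort, column) {
  d <- cohortData(cohort)
  if (!column %in% names(d)) stop("no such column: ", column)
  x <- d[[column]]
  nonpos <- !is.na(x) & x <= 0
  x[nonpos] <- NA
  newcol <- paste0("ln_", column)
  d[[newcol]] <- log(x)
  ml <- cohort@missingLog
  ml[newcol] <- sum(nonpos)
  methods::new("Cohort", data = d, missingLog = ml)
}

#' HOMA-IR insulin-resistance index
#'
#' (fasting glucose [mmol/L] x fasting insulin [uIU/mL]) / 22.5. Glucose given
#' in mg/dL is converted to mmol/L with divisor 18.016 (the molar mass of
#' glucose in g/mol scaled to dL).
#'
#' @param glucose fasting glucose.
#' @param insulin fasting insulin, uIU/mL.
#' @param glucoseUnit "mg/dL" (default, converted) or "mmol/L" (used as is).
#' @return numeric HOMA-IR.
#' @export
deriveHomaIr <- function(glucose, insulin, glucoseUnit = c("mg/dL", "mmol/L")) {
  glucoseUnit <- match.arg(glucoseUnit)
  if (any(glucose < 0, na.rm = TRUE) || any(insulin < 0, na.rm = TRUE))
    stop("glucose and insulin must be nonnegative")
  g <- if (glucoseUnit == "mg/dL") glucose / 18.016 else glucose
  g * insulin / 22.5
}

#' Align a Cohort and a GenotypeMatrix on shared samples
#'
#' Restricts both objects to the sorted intersection of their sample ids, in
#' the same order. Dropped samples are reported via message.
#'
#' @param cohort a Cohort.
#' @param genotypes a GenotypeMatrix.
#' @return list(cohort = , genotypes = ).
#' @export
alignCohort <- function(cohort, genotypes) {
  ids <- sort(intersect(sampleIds(cohort), sampleIds(genotypes)))
  if (length(ids) == 0) stop("no overlapping sample ids between cohort and genotypes")
  dropPheno <- setdiff(sampleIds(cohort), ids)
  dropGeno <- setdiff(sampleIds(genotypes), ids)
  if (length(dropPheno) || length(dropGeno))
    message("alignCohort: dropped ", length(dropPheno), " phenotype-only and ",
            length(dropGeno), " genotype-only sample(s)")
  d <- cohortData(cohort)
  d <- d[match(ids, d$sample_id), , drop = FALSE]
  rownames(d) <- NULL
  g <- dosages(genotypes)[ids, , drop = FALSE]
  list(cohort = methods::new("Cohort", data = d, missingLog = cohort@missingLog),
       genotypes = methods::new("GenotypeMatrix", dosages = g,
                                variants = variantInfo(genotypes)))
}
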
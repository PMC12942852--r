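#' Pipeline configuration
#'
#' Collects every threshold and covariate set of the full analysis with the
#' study's stated values as defaults: QC thresholds (sample call 0.90, marker
#' call 0.95, MAF 0.01, HWE p 0.001), LD pruning (250-variant window, step
#' 50, r^2 0.5), the suggestive discovery threshold 1e-5, the screening level
#' 0.05, the weak-instrument bar F > 10, K = 10 cross-fitting folds, and the
#' covariate sets (scan: age + sex; weights/screening/second stage: age +
#' sex + BMI).
#'
#' @param simulation a \code{\link{simulationConfig}} (or NULL when cohort
#'   and genotypes are passed to \code{\link{runPipeline}} directly).
#' @param ... overrides for any default listed above; see the returned list.
#' @return a list of class \code{pipelineConfig}.
#' @export
pipelineConfig <- function(simulation = simulationConfig("causal"), ...) {
  cfg <- list(
    simulation = simulation,
    sampleCall = 0.90, markerCall = 0.95, mafMin = 0.01, hwePmin = 0.001,
    pruneWindow = 250, pruneStep = 50, pruneR2 = 0.5,
    suggestiveAlpha = 1e-5, screenAlpha = 0.05, fMin = 10,
    K = 10, bootstrapB = 0,
    scanCovars = c("age", "sex"),
    covars = c("age", "sex", "bmi"),
    candidates = NULL,     # prespecified candidate ids; NULL = scan discovery
    expandedVariant = NULL,
    seed = if (is.null(simulation)) 1L else simulation@seed)
  utils::modifyList(cfg, list(...))
}

writeJson <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

estimateRow <- function(est) {
  data.frame(label = est@label, model = est@model, method = est@method,
             estimate = est@estimate, or_value = est@orValue,
             ci_low = est@ciLow, ci_high = est@ciHigh, p = est@p,
             n = est@n, first_stage_f = est@firstStageF,
             first_stage_r2 = est@firstStageR2, stringsAsFactors = FALSE)
}

#' Run the full pipeline
#'
#' Cohort simulation (or supplied data) -> genotype QC -> additive scan ->
#' suggestive hits -> LD pruning of candidates -> prespecified instrument
#' screening -> GRS, cross-fitted GRS and (optionally) expanded GRS -> MR
#' estimates (2SPS and 2SRI, crude and adjusted, per instrument and per
#' score; overidentified 2SLS with Sargan and Wu-Hausman diagnostics when at
#' least two instruments are retained) -> the observational arm -> a
#' forest-style comparative table. Every stage writes its output under
#' \code{outDir} together with a manifest sufficient to re-run.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if needed).
#' @param cohort,genotypes optional data, bypassing simulation.
#' @return invisibly, a list with every stage's in-memory result.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = tempfile("tgmr_"),
                        cohort = NULL, genotypes = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- "cohort"
  res <- tryCatch({
    truth <- NULL
    if (is.null(cohort)) {
      sim <- simulateCohort(config$simulation)
      cohort <- sim$cohort; genotypes <- sim$genotypes; truth <- sim$truth
    }
    if (!"ln_tg" %in% names(cohortData(cohort))) {
      if (!"tg" %in% names(cohortData(cohort)))
        stop("cohort lacks the exposure column (tg / ln_tg)")
      cohort <- deriveLn(cohort, "tg")
    }
    al <- alignCohort(cohort, genotypes)
    cohort <- al$cohort; genotypes <- al$genotypes
    writePhenotypeTable(cohort, file.path(outDir, "phenotypes.tsv"))

    stage <- "qc"
    qc <- qcPipeline(genotypes, config$sampleCall, config$markerCall,
                     config$mafMin, config$hwePmin)
    writeJson(qc$report[setdiff(names(qc$report), "removed")],
              file.path(outDir, "qc_report.json"))
    genotypes <- qc$genotypes
    al <- alignCohort(cohort, genotypes)
    cohort <- al$cohort; genotypes <- al$genotypes

    stage <- "scan"
    scan <- additiveScan(genotypes, cohort, covars = config$scanCovars)
    utils::write.table(format(scan, digits = 10), file.path(outDir, "scan.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hits <- suggestiveHits(scan, config$suggestiveAlpha)

    stage <- "screen"
    candidates <- config$candidates %||% hits
    if (!length(candidates))
      stop("no candidate instruments at the suggestive threshold")
    keepIdx <- match(candidates, variantInfo(genotypes)$id)
    candGeno <- methods::new("GenotypeMatrix",
      dosages = dosages(genotypes)[, keepIdx, drop = FALSE],
      variants = variantInfo(genotypes)[keepIdx, , drop = FALSE])
    ord <- order(variantInfo(candGeno)$chrom, variantInfo(candGeno)$pos)
    candGeno <- methods::new("GenotypeMatrix",
      dosages = dosages(candGeno)[, ord, drop = FALSE],
      variants = variantInfo(candGeno)[ord, , drop = FALSE])
    pr <- ldPrune(candGeno, config$pruneWindow, config$pruneStep, config$pruneR2)
    candidates <- variantInfo(pr$genotypes)$id
    instr <- selectInstruments(genotypes, cohort, candidates,
                               covars = config$covars, fMin = config$fMin,
                               alpha = config$screenAlpha)
    utils::write.table(instrumentTable(instr), file.path(outDir, "instruments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    audit <- auditTrail(instr)
    writeLines(vapply(seq_len(nrow(audit)), function(i)
      jsonlite::toJSON(as.list(audit[i, ]), auto_unbox = TRUE, na = "null"),
      character(1)), file.path(outDir, "audit.jsonl"))

    stage <- "grs"
    grs <- buildGrs(genotypes, instr)
    crossfit <- crossfitGrs(genotypes, cohort, instrumentTable(instr)$id,
                            K = config$K, seed = childSeed(config$seed, 71),
                            covars = config$covars)
    expanded <- NULL
    if (!is.null(config$expandedVariant)) {
      expandedSet <- expandedGrs(genotypes, cohort, instr,
                                 config$expandedVariant, fMin = config$fMin)
      expanded <- buildGrs(genotypes, expandedSet, includeSensitivity = TRUE)
    }

    stage <- "mr"
    ivTab <- instrumentTable(instr)
    ests <- list()
    for (model in c("crude", "adjusted")) {
      cv <- if (model == "crude") character(0) else config$covars
      obs <- logisticOr(cohort, "ln_tg",
                        covars = if (model == "crude") NULL else config$covars)
      ests[[paste0("obs_", model)]] <- mkEstimate(
        "observational", "measured ln(TG)", model, obs$estimate, obs$se,
        obs$n, cv)
      for (i in seq_len(nrow(ivTab))) {
        dose <- orientedDosage(genotypes, ivTab$id[i], ivTab$flipped[i])
        ests[[paste(ivTab$id[i], model)]] <-
          twoStagePS(cohort, dose, cv, label = ivTab$id[i])
        ests[[paste(ivTab$id[i], model, "2sri")]] <-
          twoStageRI(cohort, dose, cv, label = ivTab$id[i])
      }
      ests[[paste("grs", model)]] <- twoStagePS(cohort, grs, cv, label = "GRS")
      ests[[paste("grs", model, "2sri")]] <-
        twoStageRI(cohort, grs, cv, label = "GRS")
      ests[[paste("cf", model)]] <-
        twoStagePS(cohort, crossfit, cv, label = "crossfit-GRS")
      if (!is.null(expanded))
        ests[[paste("exp", model)]] <-
          twoStagePS(cohort, expanded, cv, label = "expanded-GRS")
    }

    diagnostics <- NULL
    if (nrow(ivTab) >= 2) {
      doseList <- stats::setNames(lapply(seq_len(nrow(ivTab)), function(i)
        orientedDosage(genotypes, ivTab$id[i], ivTab$flipped[i])), ivTab$id)
      tsls <- twoSls(cohort, doseList, config$covars, label = "2SLS")
      ests[["tsls"]] <- tsls
      sg <- sarganTest(tsls)
      wh <- wuHausmanTest(cohort, doseList, config$covars)
      diagnostics <- list(sargan_stat = sg$stat, sargan_df = sg$df,
                          sargan_p = sg$p, wu_hausman_stat = wh$stat,
                          wu_hausman_p = wh$p)
      writeJson(diagnostics, file.path(outDir, "diagnostics.json"))
    }

    stage <- "observational"
    vs <- data.frame(variable = c("age", "bmi", "tg", "glucose", "insulin",
                                  "hdl", "ldl", "homa_ir"),
                     ln_flag = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                                 TRUE), stringsAsFactors = FALSE)
    vs <- vs[vs$variable %in% names(cohortData(cohort)), , drop = FALSE]
    baseline <- baselineTable(cohort, vs, covars = config$covars)
    utils::write.table(format(baseline, digits = 10),
                       file.path(outDir, "baseline.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    negctl <- negativeControlScan(instr, genotypes, cohort,
                                  intersect(c("hdl", "ldl", "glucose"),
                                            names(cohortData(cohort))),
                                  covars = config$covars)
    utils::write.table(format(negctl, digits = 10),
                       file.path(outDir, "negative_controls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "report"
    rows <- do.call(rbind, lapply(ests, estimateRow))
    rownames(rows) <- NULL
    ft <- forestTable(rows)
    utils::write.table(format(ft$table, digits = 10),
                       file.path(outDir, "forest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(ft$text, file.path(outDir, "forest.txt"))

    manifest <- list(
      package_version = as.character(utils::packageVersion("tgmr")),
      seed = config$seed,
      config = config[setdiff(names(config), "simulation")],
      simulation = if (is.null(config$simulation)) NULL else {
        sn <- methods::slotNames(config$simulation)
        lapply(stats::setNames(sn, sn),
               function(s) methods::slot(config$simulation, s))
      },
      n_candidates = length(candidates),
      n_instruments = nrow(ivTab))
    writeJson(manifest, file.path(outDir, "manifest.json"))

    list(cohort = cohort, genotypes = genotypes, truth = truth,
         qcReport = qc$report, scan = scan, hits = hits,
         instruments = instr, grs = grs, crossfit = crossfit,
         expanded = expanded, estimates = ests, diagnostics = diagnostics,
         baseline = baseline, negativeControls = negctl, forest = ft,
         outDir = outDir)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Forest-style comparative table
#'
#' Renders estimate rows (observational first, then per-SNP, then score
#' rows) as a fixed-width text block and a TSV-ready data.frame with OR (95%
#' CI) and p formatted to two decimals, mirroring a forest plot's row
#' structure.
#'
#' @param rows data.frame of estimate rows (see the pipeline's estimates
#'   output); must have label, model, method, or_value or estimate, ci_low,
#'   ci_high, p, n.
#' @return list(table = data.frame, text = character lines).
#' @export
forestTable <- function(rows) {
  if (!nrow(rows)) stop("no estimate rows to render")
  labRank <- function(l, m) {
    base <- ifelse(m == "observational", 0,
            ifelse(grepl("^expanded", l), 4,
            ifelse(grepl("^crossfit", l), 3,
            ifelse(l == "GRS", 2, 1))))
    base
  }
  rows <- rows[order(labRank(rows$label, rows$method), rows$label,
                     rows$model, rows$method), , drop = FALSE]
  val <- ifelse(is.na(rows$or_value), rows$estimate, rows$or_value)
  scale <- ifelse(is.na(rows$or_value), "slope", "OR")
  tab <- data.frame(
    label = rows$label, model = rows$model, method = rows$method,
    scale = scale,
    estimate = sprintf("%.2f", val),
    ci = sprintf("%.2f-%.2f", rows$ci_low, rows$ci_high),
    p = ifelse(rows$p < 0.001, "<0.001", sprintf("%.3f", rows$p)),
    n = rows$n, stringsAsFactors = FALSE)
  text <- c(sprintf("%-18s %-9s %-14s %6s %15s %8s %6s",
                    "label", "model", "method", "est", "95% CI", "p", "n"),
            sprintf("%-18s %-9s %-14s %6s %15s %8s %6d",
                    tab$label, tab$model, tab$method, tab$estimate, tab$ci,
                    tab$p, tab$n))
  list(table = tab, text = text)
}
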
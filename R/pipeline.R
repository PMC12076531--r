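# End-to-end pipeline: ingest -> preprocess -> calibrate -> integrate,
# driven by one declarative config so a run is reproducible between labs.
# Every decision taken along the way (dialect, chosen method and
# normalization, dropped anchors, enrichment factors, seed) is written to
# run.log; outputs carry no timestamps, so identical config + seed gives
# byte-identical files.

.PIPELINE_DEFAULTS <- list(
  report = NULL, anchors = NULL, params = NULL, standards = NULL,
  fasta = NULL, engine = "auto", method = "auto", normalization = "auto",
  impute = TRUE, removeContaminants = TRUE, minValidFraction = 2 / 3,
  downshiftSd = 1.8, downshiftWidth = 0.3, seed = 1L,
  cultureVolumeUnit = "uL", outputDir = "."
)

#' Assemble a pipeline configuration
#'
#' @param config a named list, or the path to a YAML file with the same
#'   keys. Mandatory: `report` and `anchors` (paths). Optional: `params`
#'   (experimental parameters table — without it the pipeline stops after
#'   calibration and emits fmol at MS scale only), `standards` (enrichment
#'   standards table), `fasta` (protein sequences for molecular weights),
#'   `engine`, `method`/`normalization` (`"auto"` lets [consult()] choose),
#'   `impute`, `removeContaminants`, `minValidFraction`, `downshiftSd`,
#'   `downshiftWidth`, `seed`, `cultureVolumeUnit`, `outputDir`.
#' @param ... individual keys overriding the config (the CLI maps its
#'   flags here).
#' @return the completed config list.
#' @export
pipelineConfig <- function(config = list(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  over <- list(...)
  config[names(over)] <- over
  known <- names(.PIPELINE_DEFAULTS)
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  out <- .PIPELINE_DEFAULTS
  out[names(config)] <- config
  if (is.null(out$report) || is.null(out$anchors))
    stop("config needs at least 'report' and 'anchors'", call. = FALSE)
  out
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full quantification pipeline
#'
#' Chains ingestion, preprocessing (flag removal, group inference, validity
#' filtering, normalization, imputation), anchor calibration (with
#' [consult()] choosing the intensity method and normalization when set to
#' `"auto"`), and — when a parameters table is configured — enrichment
#' correction and conversion to absolute units.
#'
#' Outputs written to `outputDir`: `preprocessed.tsv` (the processed
#' intensity table with `imputed_<sample>` mark columns), `calibration.json`
#' (every fitted calibration model), `absolute.tsv` (long-format
#' abundances) and `run.log`.
#'
#' @param config a config list or YAML path, see [pipelineConfig()].
#' @param ... overrides passed to [pipelineConfig()].
#' @return (invisibly) a list with the final [AbsoluteQuantResult-class]
#'   (`result`), the processed [QuantReport-class] (`report`), the chosen
#'   `method` and `normalization`, the [SampleGrouping-class] (`grouping`),
#'   any [EnrichmentFactor-class]s (`factors`) and the output paths.
#' @export
runPipeline <- function(config = list(), ...) {
  cfg <- pipelineConfig(config, ...)
  dir.create(cfg$outputDir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  say("seed: %d", as.integer(cfg$seed))
  report <- readReport(cfg$report, cfg$engine)
  say("ingest: %d protein groups from '%s' (%s dialect)",
      nrow(report@rowData), cfg$report, report@engine)
  catalog <- inspectReport(report)
  say("ingest: methods detected: %s",
      paste(names(catalogMethods(catalog)), collapse = ", "))

  if (isTRUE(cfg$removeContaminants)) {
    before <- nrow(report@rowData)
    report <- removeFlagged(report)
    say("preprocess: removed %d flagged rows", before - nrow(report@rowData))
  }

  anchors <- readAnchors(cfg$anchors)
  say("anchors: %d entries from '%s'", length(anchors), cfg$anchors)

  method <- cfg$method
  normalization <- cfg$normalization
  if (identical(method, "auto") || identical(normalization, "auto")) {
    cand <- consult(report,
                    anchors,
                    candidateMethods = if (identical(method, "auto"))
                      intensityMethods(report) else method,
                    candidateNormalizations = if (identical(normalization, "auto"))
                      c("none", "median", "quantile", "total_sum")
                    else normalization)
    method <- cand$method[1L]
    normalization <- cand$normalization[1L]
    say("consult: chose method '%s', normalization '%s' (mean R^2 = %.4f)",
        method, normalization, cand$meanRSquared[1L])
  }

  grouping <- inferGroups(sampleLabels(report, method))
  say("grouping: %s", paste(vapply(names(groupList(grouping)), function(g)
    sprintf("%s={%s}", g, paste(groupList(grouping)[[g]], collapse = ",")),
    character(1)), collapse = "; "))

  before <- nrow(report@rowData)
  report <- withCallingHandlers(
    filterValid(report, grouping, method, cfg$minValidFraction),
    warning = function(w) { say("filter: %s", conditionMessage(w))
      invokeRestart("muffleWarning") })
  say("filter: %d of %d proteins kept (min valid fraction %.3f)",
      nrow(report@rowData), before, cfg$minValidFraction)

  report <- normalizeIntensities(report, normalization)
  say("normalize: %s", normalization)
  if (isTRUE(cfg$impute)) {
    report <- withCallingHandlers(
      imputeMissing(report, cfg$downshiftSd, cfg$downshiftWidth, cfg$seed),
      warning = function(w) { say("impute: %s", conditionMessage(w))
        invokeRestart("muffleWarning") })
    say("impute: gaussian downshift (sd %.2f, width %.2f, seed %d)",
        cfg$downshiftSd, cfg$downshiftWidth, as.integer(cfg$seed))
  } else say("impute: disabled")

  result <- withCallingHandlers(
    quantifyReport(report, anchors, method),
    warning = function(w) { say("calibrate: %s", conditionMessage(w))
      invokeRestart("muffleWarning") })
  for (m in calibrationModels(result)) {
    say("calibrate: sample %s: log10(I) = %.4f + %.4f log10(fmol), R^2 %.4f, n %d%s",
        paste(m@sample, collapse = "+"), m@intercept, m@slope, m@rSquared,
        m@nAnchorsUsed,
        if (length(m@anchorsExcluded))
          paste0(" (excluded: ", paste(m@anchorsExcluded, collapse = ","), ")")
        else "")
  }

  factors <- list()
  if (!is.null(cfg$params)) {
    params <- readParams(cfg$params, cfg$cultureVolumeUnit)
    standards <- if (!is.null(cfg$standards))
      readEnrichmentStandards(cfg$standards)
    p <- paramsTable(params)
    for (i in which(p$enrichment)) {
      cond <- p$condition[i]
      f <- withCallingHandlers(
        if (!is.na(p$stdDilution[i]) && !is.null(standards))
          computeEnrichment(result, params, standards, cond)
        else srmEnrichment(result, params, cond),
        warning = function(w) { say("enrichment: %s", conditionMessage(w))
          invokeRestart("muffleWarning") })
      factors[[cond]] <- f
      say("enrichment: condition '%s' factor %.4f (%d standards, %s)",
          cond, f@factor, f@nStandards, f@basis)
    }
    mw <- molWeights(report)
    if (all(is.na(mw)) && !is.null(cfg$fasta)) {
      fw <- molWeightsFromFasta(cfg$fasta)
      mw <- fw[sub(";.*$", "", proteinIds(report))]
      names(mw) <- proteinIds(report)
      say("molecular weights: computed from FASTA '%s'", cfg$fasta)
    }
    mw <- mw[!is.na(mw)]
    result <- withCallingHandlers(
      toAbsolute(result, params, factors, mw),
      warning = function(w) { say("integrate: %s", conditionMessage(w))
        invokeRestart("muffleWarning") })
    say("integrate: absolute units filled for %d conditions",
        length(unique(quantTable(result)$condition)))
  } else {
    say("integrate: no parameters table; stopping after calibration (fmolMS only)")
  }

  # outputs ------------------------------------------------------------
  mat <- intensityMatrix(report, method)
  mask <- imputedMask(report, method)
  pre <- data.frame(proteinId = proteinIds(report), check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (s in colnames(mat)) pre[[s]] <- mat[, s]
  for (s in colnames(mat)) pre[[paste0("imputed_", s)]] <- mask[, s]
  prePath <- .writeTsv(pre, file.path(cfg$outputDir, "preprocessed.tsv"))

  calPath <- file.path(cfg$outputDir, "calibration.json")
  jsonlite::write_json(lapply(calibrationModels(result), function(m) list(
    sample = m@sample, method = m@method, slope = m@slope,
    intercept = m@intercept, r_squared = m@rSquared,
    n_anchors_used = m@nAnchorsUsed, anchors_excluded = m@anchorsExcluded
  )), calPath, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  absPath <- .writeTsv(quantTable(result),
                       file.path(cfg$outputDir, "absolute.tsv"))
  logPath <- file.path(cfg$outputDir, "run.log")
  writeLines(log, logPath)

  invisible(list(result = result, report = report, method = method,
                 normalization = normalization, grouping = grouping,
                 factors = factors,
                 paths = list(preprocessed = prePath, calibration = calPath,
                              absolute = absPath, log = logPath)))
}
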
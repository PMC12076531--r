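#' Accessors for QuantReport objects
#'
#' @param x a [QuantReport-class].
#' @param method an intensity-method name; defaults to the first method.
#'
#' @return `proteinIds` and `firstAccessions` return character vectors (the
#'   latter truncates semicolon-separated protein groups to their first
#'   accession, for matching against single-accession anchor tables);
#'   `intensityMethods` a character vector of detected methods;
#'   `sampleLabels` the sample labels of one method; `intensityMatrix` the
#'   proteins x samples numeric matrix of one method (`NA` = missing);
#'   `imputedMask` the parallel logical matrix of imputation marks (all
#'   `FALSE` before imputation); `molWeights` a numeric vector of molecular
#'   weights in kDa (NA where the report has none).
#'
#' @name QuantReport-accessors
NULL

#' @rdname QuantReport-accessors
setMethod("proteinIds", "QuantReport", function(x) x@rowData$proteinId)

#' @rdname QuantReport-accessors
setMethod("firstAccessions", "QuantReport", function(x)
  sub(";.*$", "", x@rowData$proteinId))

#' @rdname QuantReport-accessors
setMethod("intensityMethods", "QuantReport", function(x) names(x@intensities))

.checkMethod <- function(x, method) {
  if (missing(method) || is.null(method)) return(names(x@intensities)[1L])
  if (!method %in% names(x@intensities))
    stop(sprintf("unknown intensity method '%s'; available: %s", method,
                 paste(names(x@intensities), collapse = ", ")), call. = FALSE)
  method
}

#' @rdname QuantReport-accessors
setMethod("sampleLabels", "QuantReport", function(x, method) {
  colnames(x@intensities[[.checkMethod(x, method)]])
})

#' @rdname QuantReport-accessors
setMethod("intensityMatrix", "QuantReport", function(x, method) {
  x@intensities[[.checkMethod(x, method)]]
})

#' @rdname QuantReport-accessors
setMethod("imputedMask", "QuantReport", function(x, method) {
  method <- .checkMethod(x, method)
  if (!is.null(x@imputed[[method]])) return(x@imputed[[method]])
  mat <- x@intensities[[method]]
  array(FALSE, dim = dim(mat), dimnames = dimnames(mat))
})

#' @rdname QuantReport-accessors
setMethod("molWeights", "QuantReport", function(x) {
  stats::setNames(x@rowData$molWeightKDa, x@rowData$proteinId)
})

#' @rdname QuantReport-accessors
#' @export
flagTable <- function(x) {
  stopifnot(is(x, "QuantReport"))
  x@rowData[, c("proteinId", "isContaminant", "isReverse", "isSiteOnly")]
}

setMethod("dim", "QuantReport", function(x)
  c(nrow(x@rowData), ncol(x@intensities[[1L]])))

setMethod("show", "QuantReport", function(object) {
  cat(sprintf("QuantReport (%s dialect): %d protein groups\n",
              object@engine, nrow(object@rowData)))
  for (m in names(object@intensities)) {
    mat <- object@intensities[[m]]
    cat(sprintf("  method '%s': %d samples [%s]\n", m, ncol(mat),
                paste(utils::head(colnames(mat), 4L),
                      collapse = ", ")))
  }
  nf <- sum(object@rowData$isContaminant | object@rowData$isReverse |
              object@rowData$isSiteOnly)
  cat(sprintf("  flagged rows: %d; suggested ID column: %s\n",
              nf, object@idColumn))
  invisible(NULL)
})

#' Accessor for SampleGrouping
#' @param x a [SampleGrouping-class].
#' @return named list, group label -> member sample labels.
#' @name SampleGrouping-accessors
#' @rdname SampleGrouping-accessors
setMethod("groupList", "SampleGrouping", function(x) x@groups)

setMethod("show", "SampleGrouping", function(object) {
  cat(sprintf("SampleGrouping: %d groups\n", length(object@groups)))
  for (g in names(object@groups))
    cat(sprintf("  %s: %s\n", g, paste(object@groups[[g]], collapse = ", ")))
  invisible(NULL)
})

#' Accessor for AnchorSet
#' @param x an [AnchorSet-class].
#' @return named numeric vector, accession -> spiked fmol.
#' @name AnchorSet-accessors
#' @rdname AnchorSet-accessors
setMethod("anchorAmounts", "AnchorSet", function(x) x@amounts)

setMethod("length", "AnchorSet", function(x) length(x@amounts))

setMethod("show", "AnchorSet", function(object) {
  rng <- range(object@amounts)
  cat(sprintf("AnchorSet: %d anchors, %.3g-%.3g fmol (%s)\n",
              length(object@amounts), rng[1], rng[2], object@sourcePath))
  invisible(NULL)
})

#' Accessor for CalibrationModel
#' @param x a [CalibrationModel-class].
#' @return named numeric vector with `slope`, `intercept`, `rSquared`.
#' @name CalibrationModel-accessors
#' @rdname CalibrationModel-accessors
setMethod("calibrationCoefficients", "CalibrationModel", function(x)
  c(slope = x@slope, intercept = x@intercept, rSquared = x@rSquared))

setMethod("show", "CalibrationModel", function(object) {
  cat(sprintf(
    "CalibrationModel [%s, %s, %s]\n  log10(I) = %.4f + %.4f log10(fmol), R^2 = %.4f (n = %d anchors)\n",
    object@method, object@normalization, paste(object@sample, collapse = "+"),
    object@intercept, object@slope, object@rSquared, object@nAnchorsUsed))
  if (length(object@anchorsExcluded))
    cat(sprintf("  excluded: %s\n", paste(object@anchorsExcluded, collapse = ", ")))
  invisible(NULL)
})

#' Accessors for AbsoluteQuantResult
#' @param x an [AbsoluteQuantResult-class].
#' @return `quantTable` the long-format data.frame of abundances;
#'   `calibrationModels` the list of fitted [CalibrationModel-class]s.
#' @name AbsoluteQuantResult-accessors
#' @rdname AbsoluteQuantResult-accessors
setMethod("quantTable", "AbsoluteQuantResult", function(x) x@quant)

#' @rdname AbsoluteQuantResult-accessors
setMethod("calibrationModels", "AbsoluteQuantResult", function(x) x@models)

setMethod("show", "AbsoluteQuantResult", function(object) {
  q <- object@quant
  cat(sprintf("AbsoluteQuantResult: %d proteins x %d samples (method '%s')\n",
              length(unique(q$proteinId)), length(unique(q$sample)),
              object@method))
  units <- intersect(c("fmolMS", "fmolTotal", "ngPerUg", "moleculesPerCell"),
                     names(q))
  filled <- units[vapply(units, function(u) any(is.finite(q[[u]])), logical(1))]
  cat(sprintf("  units filled: %s\n", paste(filled, collapse = ", ")))
  invisible(NULL)
})

setMethod("as.data.frame", "AbsoluteQuantResult", function(x, ...) x@quant)

#' Accessor for ExperimentalParams
#' @param x an [ExperimentalParams-class].
#' @return the validated parameters data.frame (one row per condition).
#' @name ExperimentalParams-accessors
#' @rdname ExperimentalParams-accessors
setMethod("paramsTable", "ExperimentalParams", function(x) x@params)

setMethod("show", "ExperimentalParams", function(object) {
  p <- object@params
  cat(sprintf("ExperimentalParams: %d conditions (%s), culture volume in %s\n",
              nrow(p), paste(p$condition, collapse = ", "),
              object@cultureVolumeUnit))
  invisible(NULL)
})

#' Accessor for EnrichmentFactor
#' @param x an [EnrichmentFactor-class].
#' @return the numeric enrichment factor.
#' @name EnrichmentFactor-accessors
#' @rdname EnrichmentFactor-accessors
setMethod("enrichmentValue", "EnrichmentFactor", function(x) x@factor)

setMethod("show", "EnrichmentFactor", function(object) {
  cat(sprintf("EnrichmentFactor: %.4g for '%s' (%d standards, basis %s)\n",
              object@factor, object@condition, object@nStandards, object@basis))
  invisible(NULL)
})
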
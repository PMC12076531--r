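#' @import methods
NULL

#' QuantReport: a protein-groups report with per-method intensity matrices
#'
#' One row per protein group. Intensity columns of the source report are
#' split into one numeric matrix per intensity method (iBAQ, LFQ intensity,
#' PG.Quantity, ...), proteins x samples, with missing/zero values stored as
#' `NA`. Row metadata carries the protein identifier, optional gene name and
#' molecular weight, and the contaminant/reverse/site-only flags of the
#' source dialect.
#'
#' @slot rowData data.frame with columns `proteinId`, `geneName`,
#'   `molWeightKDa`, `isContaminant`, `isReverse`, `isSiteOnly`.
#' @slot intensities named list of numeric matrices, one per intensity
#'   method; all values are positive or `NA`.
#' @slot imputed named list of logical matrices marking imputed cells,
#'   parallel to `intensities` (empty until [imputeMissing()] runs).
#' @slot engine character, the search-engine dialect the report was read as.
#' @slot idColumn character, the suggested protein-identifier column.
#'
#' @seealso [readReport()], [inspectReport()]
#' @export
setClass("QuantReport",
  representation(
    rowData = "data.frame",
    intensities = "list",
    imputed = "list",
    engine = "character",
    idColumn = "character"
  )
)

setValidity("QuantReport", function(object) {
  rd <- object@rowData
  msg <- character()
  needed <- c("proteinId", "geneName", "molWeightKDa",
              "isContaminant", "isReverse", "isSiteOnly")
  if (!all(needed %in% names(rd)))
    msg <- c(msg, paste("rowData must contain:", paste(needed, collapse = ", ")))
  else if (any(is.na(rd$proteinId) | !nzchar(rd$proteinId)))
    msg <- c(msg, "every row needs a non-empty proteinId")
  if (length(object@intensities) == 0L)
    msg <- c(msg, "at least one intensity method is required")
  if (is.null(names(object@intensities)) || any(!nzchar(names(object@intensities))))
    msg <- c(msg, "intensity methods must be named")
  for (m in names(object@intensities)) {
    mat <- object@intensities[[m]]
    if (!is.matrix(mat) || !is.numeric(mat))
      msg <- c(msg, sprintf("intensities[['%s']] must be a numeric matrix", m))
    else {
      if (nrow(mat) != nrow(rd))
        msg <- c(msg, sprintf("intensities[['%s']] row count differs from rowData", m))
      if (ncol(mat) < 1L)
        msg <- c(msg, sprintf("method '%s' has no sample columns", m))
      if (any(mat <= 0, na.rm = TRUE))
        msg <- c(msg, sprintf("intensities[['%s']] must be positive or NA", m))
      if (is.null(colnames(mat)))
        msg <- c(msg, sprintf("intensities[['%s']] needs sample labels as colnames", m))
    }
  }
  for (m in names(object@imputed)) {
    if (!m %in% names(object@intensities))
      msg <- c(msg, sprintf("imputed mask for unknown method '%s'", m))
    else if (!identical(dim(object@imputed[[m]]), dim(object@intensities[[m]])))
      msg <- c(msg, sprintf("imputed mask for '%s' has wrong dimensions", m))
  }
  if (length(msg)) msg else TRUE
})

#' IntensityCatalog: detected intensity methods and suggested ID column
#'
#' @slot methods named list: intensity-method name -> character vector of
#'   sample labels (method prefixes already stripped).
#' @slot suggestedIdColumn character, the protein-identifier column the
#'   ingestion suggests.
#' @seealso [inspectReport()]
#' @export
setClass("IntensityCatalog",
  representation(methods = "list", suggestedIdColumn = "character")
)

setValidity("IntensityCatalog", function(object) {
  labs <- unlist(object@methods, use.names = FALSE)
  if (length(object@methods) == 0L) return("catalog must list at least one method")
  if (anyDuplicated(labs)) {
    # a sample label may legitimately appear under several methods (iBAQ A1,
    # LFQ intensity A1); duplication WITHIN a method is the error
    for (m in names(object@methods))
      if (anyDuplicated(object@methods[[m]]))
        return(sprintf("duplicated sample label within method '%s'", m))
  }
  TRUE
})

#' SampleGrouping: partition of sample labels into replicate groups
#'
#' @slot groups named list: group label -> character vector of member sample
#'   labels. The groups partition the sample set.
#' @slot singletonPolicyApplied logical, `TRUE` if any label without a
#'   replicate partner was kept as its own group.
#' @seealso [inferGroups()]
#' @export
setClass("SampleGrouping",
  representation(groups = "list", singletonPolicyApplied = "logical")
)

setValidity("SampleGrouping", function(object) {
  members <- unlist(object@groups, use.names = FALSE)
  if (anyDuplicated(members)) return("groups must not overlap")
  if (is.null(names(object@groups))) return("groups must be named")
  TRUE
})

#' AnchorSet: spiked anchor proteins and their amounts
#'
#' Maps anchor-protein accessions to the amount (fmol) spiked at the
#' MS-injection level, e.g. the UPS2 dynamic range standard.
#'
#' @slot amounts named numeric vector, accession -> fmol (> 0).
#' @slot sourcePath character provenance string.
#' @seealso [readAnchors()], [fitAnchors()]
#' @export
setClass("AnchorSet",
  representation(amounts = "numeric", sourcePath = "character")
)

setValidity("AnchorSet", function(object) {
  a <- object@amounts
  if (length(a) == 0L) return("anchor set is empty")
  if (is.null(names(a)) || any(!nzchar(names(a)))) return("anchors must be named by accession")
  if (anyDuplicated(names(a))) return("duplicate anchor accession")
  if (any(!is.finite(a) | a <= 0)) return("anchor amounts must be positive and finite")
  TRUE
})

#' CalibrationModel: a fitted log-log anchor calibration
#'
#' Ordinary least squares of log10(intensity) on log10(spiked fmol) over the
#' anchor proteins found in one sample (or pooled over samples).
#'
#' @slot slope,intercept numeric regression coefficients in log10-log10 space.
#' @slot rSquared numeric in [0, 1], computed on the points actually fitted.
#' @slot nAnchorsUsed integer, number of anchor points in the fit.
#' @slot method character, intensity method the fit used.
#' @slot normalization character, normalization applied before fitting.
#' @slot sampleScope character, `"per-sample"` or `"pooled"`.
#' @slot sample character, sample label(s) the fit covers.
#' @slot anchorsExcluded character, accessions dropped (missing, imputed or
#'   ambiguously matched).
#' @seealso [fitAnchors()], [estimateAmounts()]
#' @export
setClass("CalibrationModel",
  representation(
    slope = "numeric", intercept = "numeric", rSquared = "numeric",
    nAnchorsUsed = "integer", method = "character",
    normalization = "character", sampleScope = "character",
    sample = "character", anchorsExcluded = "character"
  )
)

setValidity("CalibrationModel", function(object) {
  if (object@nAnchorsUsed < 3L) return("a calibration needs >= 3 anchors")
  if (!is.finite(object@slope) || object@slope == 0) return("slope must be finite and nonzero")
  if (!is.finite(object@intercept)) return("intercept must be finite")
  if (object@rSquared < 0 || object@rSquared > 1 + 1e-12) return("rSquared must lie in [0, 1]")
  TRUE
})

#' AbsoluteQuantResult: per-protein, per-sample absolute abundances
#'
#' Long-format table of calibrated abundances. [estimateAmounts()] fills
#' `fmolMS` (fmol in the injected amount); [toAbsolute()] adds the three
#' absolute units and the enrichment flag.
#'
#' @slot quant data.frame with columns `proteinId`, `sample`, `intensity`,
#'   `fmolMS`, `provenance` (`"observed"` or `"imputed"`), and after
#'   integration `condition`, `fmolTotal`, `ngPerUg`, `moleculesPerCell`,
#'   `enrichmentCorrected`.
#' @slot models list of [CalibrationModel-class] objects used.
#' @slot method character, intensity method quantified.
#' @export
setClass("AbsoluteQuantResult",
  representation(quant = "data.frame", models = "list", method = "character")
)

setValidity("AbsoluteQuantResult", function(object) {
  q <- object@quant
  needed <- c("proteinId", "sample", "intensity", "fmolMS", "provenance")
  if (!all(needed %in% names(q)))
    return(paste("quant must contain:", paste(needed, collapse = ", ")))
  if (any(q$fmolMS <= 0, na.rm = TRUE)) return("fmolMS must be positive where defined")
  if (!all(q$provenance %in% c("observed", "imputed")))
    return("provenance must be 'observed' or 'imputed'")
  TRUE
})

#' ExperimentalParams: the experimental parameters table
#'
#' One row per condition: volumes and concentrations of the digested
#' extract, amount injected into the MS, cell counts, and (optionally) the
#' enrichment settings or externally measured SRM amounts.
#'
#' @slot params data.frame with columns `condition`, `sampleVolumeUl`,
#'   `proteinConcUgPerUl`, `amountMSUg`, `cellsPerMl`, `totalCultureVolume`,
#'   `enrichment`, `enrichmentMode`, `stdDilution`, `stdVolumeUl`, and
#'   list-columns `proteinSRM`, `fmolSRM`.
#' @slot cultureVolumeUnit character, unit of `totalCultureVolume`
#'   (`"uL"` per the table schema, or `"mL"`).
#' @seealso [readParams()], [toAbsolute()]
#' @export
setClass("ExperimentalParams",
  representation(params = "data.frame", cultureVolumeUnit = "character")
)

setValidity("ExperimentalParams", function(object) {
  p <- object@params
  num <- c("sampleVolumeUl", "proteinConcUgPerUl", "amountMSUg",
           "cellsPerMl", "totalCultureVolume")
  if (!all(c("condition", num, "enrichment") %in% names(p)))
    return("params is missing mandatory columns")
  for (col in num)
    if (any(!is.na(p[[col]]) & p[[col]] <= 0))
      return(sprintf("%s must be positive", col))
  if (anyDuplicated(p$condition)) return("duplicate condition label")
  if (!object@cultureVolumeUnit %in% c("uL", "mL"))
    return("cultureVolumeUnit must be 'uL' or 'mL'")
  for (i in seq_len(nrow(p))) {
    srm <- p$proteinSRM[[i]]
    fm <- p$fmolSRM[[i]]
    if (length(srm) != length(fm))
      return(sprintf("row %d: ProteinSRM and fmolSRM lengths differ", i))
    if (isTRUE(p$enrichment[i])) {
      hasStd <- !is.na(p$enrichmentMode[i]) && !is.na(p$stdDilution[i]) &&
        !is.na(p$stdVolumeUl[i])
      if (!hasStd && length(srm) == 0L)
        return(sprintf(
          "condition '%s': Enrichment is TRUE but neither EnrichmentMode/StdDilution/StdVolume nor SRM columns are given",
          p$condition[i]))
    }
  }
  TRUE
})

#' EnrichmentStandards: spiked enrichment-standard stock concentrations
#'
#' @slot stocks named numeric vector, accession -> stock concentration
#'   (fmol/uL) of the enrichment standard.
#' @slot sourcePath character provenance string.
#' @seealso [computeEnrichment()]
#' @export
setClass("EnrichmentStandards",
  representation(stocks = "numeric", sourcePath = "character")
)

setValidity("EnrichmentStandards", function(object) {
  s <- object@stocks
  if (length(s) == 0L) return("no enrichment standards")
  if (is.null(names(s)) || anyDuplicated(names(s))) return("standards need unique accessions")
  if (any(!is.finite(s) | s <= 0)) return("stock concentrations must be positive")
  TRUE
})

#' EnrichmentFactor: estimated fold enrichment of a subproteome fraction
#'
#' @slot condition character, condition the factor applies to.
#' @slot factor positive numeric, measured / expected abundance ratio.
#' @slot nStandards integer, number of standards (or SRM proteins) used.
#' @slot basis character, `"spiked_standards"` or `"srm_supplied"`.
#' @seealso [computeEnrichment()], [srmEnrichment()]
#' @export
setClass("EnrichmentFactor",
  representation(condition = "character", factor = "numeric",
                 nStandards = "integer", basis = "character")
)

setValidity("EnrichmentFactor", function(object) {
  if (!is.finite(object@factor) || object@factor <= 0) return("factor must be positive")
  if (!object@basis %in% c("spiked_standards", "srm_supplied"))
    return("basis must be 'spiked_standards' or 'srm_supplied'")
  TRUE
})
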
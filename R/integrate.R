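# From fmol at the MS scale to absolute abundances: the experimental
# parameters table supplies extract volume, protein concentration, injected
# amount and cell counts per condition; enrichment factors correct for
# subproteome enrichment/concentration steps before converting to molecules
# per cell.

.AVOGADRO <- 6.02214076e23  # SI exact

# canonical Table-style headers, matched case-insensitively
.PARAM_COLUMNS <- c(
  Condition = "condition", SampleVolume = "sampleVolumeUl",
  ProteinConcentration = "proteinConcUgPerUl", AmountMS = "amountMSUg",
  CellsPerML = "cellsPerMl", TotalCultureVolume = "totalCultureVolume",
  ProteinSRM = "proteinSRM", fmolSRM = "fmolSRM", Enrichment = "enrichment",
  EnrichmentMode = "enrichmentMode", StdDilution = "stdDilution",
  StdVolume = "stdVolumeUl"
)
.PARAM_MANDATORY <- c("Condition", "SampleVolume", "ProteinConcentration",
                      "AmountMS", "CellsPerML", "TotalCultureVolume")

.splitList <- function(x, numeric = FALSE) {
  if (is.na(x) || !nzchar(trimws(as.character(x)))) {
    return(if (numeric) numeric(0) else character(0))
  }
  parts <- trimws(strsplit(as.character(x), ",", fixed = TRUE)[[1L]])
  if (numeric) as.numeric(parts) else parts
}

#' Read the experimental parameters table
#'
#' One row per condition with the sample-preparation details that connect
#' MS-scale amounts to the sample and the cell: volume of protein extract
#' digested (uL), protein concentration (ug/uL), amount injected into the
#' MS (ug), cells per mL of culture, total harvested culture volume, and
#' the optional enrichment settings (mode, standard stock dilution and
#' volume) or externally measured SRM accessions/fmol (comma-separated
#' lists). Headers are matched case-insensitively against the canonical
#' names (Condition, SampleVolume, ProteinConcentration, AmountMS,
#' CellsPerML, TotalCultureVolume, ProteinSRM, fmolSRM, Enrichment,
#' EnrichmentMode, StdDilution, StdVolume).
#'
#' @param path TSV or CSV file (export spreadsheets to TSV first).
#' @param cultureVolumeUnit unit of the TotalCultureVolume column. The
#'   canonical schema specifies uL (the default); pass `"mL"` for tables
#'   following the more common millilitre convention.
#' @return an [ExperimentalParams-class]. A missing mandatory column is an
#'   error naming it; `Enrichment = TRUE` without either the enrichment
#'   settings or the SRM columns is an error.
#'
#' @examples
#' p <- readParams(system.file("extdata", "experimental_params_example.tsv",
#'                             package = "anchorQuant"))
#' paramsTable(p)
#'
#' @export
readParams <- function(path, cultureVolumeUnit = c("uL", "mL")) {
  cultureVolumeUnit <- match.arg(cultureVolumeUnit)
  if (!file.exists(path)) stop("cannot read parameters table: ", path,
                               call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, fill = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  idx <- match(tolower(names(.PARAM_COLUMNS)), tolower(names(df)))
  names(idx) <- names(.PARAM_COLUMNS)
  missing <- .PARAM_MANDATORY[is.na(idx[.PARAM_MANDATORY])]
  if (length(missing))
    stop("parameters table is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)

  getCol <- function(canon, default) {
    if (is.na(idx[canon])) rep(default, nrow(df)) else df[[idx[canon]]]
  }
  p <- data.frame(
    condition = as.character(getCol("Condition", NA)),
    sampleVolumeUl = as.numeric(getCol("SampleVolume", NA)),
    proteinConcUgPerUl = as.numeric(getCol("ProteinConcentration", NA)),
    amountMSUg = as.numeric(getCol("AmountMS", NA)),
    cellsPerMl = as.numeric(getCol("CellsPerML", NA)),
    totalCultureVolume = as.numeric(getCol("TotalCultureVolume", NA)),
    enrichment = .parseBoolean(getCol("Enrichment", FALSE)),
    enrichmentMode = .parseMode(getCol("EnrichmentMode", NA)),
    stdDilution = suppressWarnings(as.numeric(getCol("StdDilution", NA))),
    stdVolumeUl = suppressWarnings(as.numeric(getCol("StdVolume", NA))),
    stringsAsFactors = FALSE
  )
  p$proteinSRM <- lapply(getCol("ProteinSRM", NA), .splitList)
  p$fmolSRM <- lapply(getCol("fmolSRM", NA), .splitList, numeric = TRUE)
  new("ExperimentalParams", params = p, cultureVolumeUnit = cultureVolumeUnit)
}

.parseBoolean <- function(x) {
  out <- tolower(trimws(as.character(x))) %in% c("true", "1")
  out[is.na(x)] <- FALSE
  out
}

.parseMode <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x) | is.na(x)] <- NA_character_
  ok <- is.na(x) | tolower(x) %in% c("enrichment", "concentration")
  if (any(!ok))
    stop("EnrichmentMode must be 'Enrichment' or 'Concentration'; got: ",
         paste(x[!ok], collapse = ", "), call. = FALSE)
  ifelse(is.na(x), NA_character_,
         ifelse(tolower(x) == "enrichment", "Enrichment", "Concentration"))
}

.paramsRow <- function(params, condition) {
  p <- params@params
  i <- which(p$condition == condition)
  if (!length(i)) stop("no parameters row for condition '", condition, "'",
                       call. = FALSE)
  p[i[1L], , drop = FALSE]
}

# Samples belonging to a condition: exact match on the condition label or
# the condition as a name prefix (Cond1 covers Cond1_1, Cond1_2, ...).
.conditionSamples <- function(samples, condition) {
  hit <- samples == condition | startsWith(samples, condition)
  if (!any(hit))
    stop("no sample of the result matches condition '", condition, "'",
         call. = FALSE)
  samples[hit]
}

#' Estimate the enrichment factor from spiked standards
#'
#' For an enriched or concentrated subproteome fraction, compares the
#' calibrated amount of each spiked enrichment standard with the amount
#' actually added. Per standard, the expected amount added to the sample is
#' `stock fmol/uL / StdDilution x StdVolume`; its expected share in the MS
#' injection scales by `AmountMS / (SampleVolume x ProteinConcentration)`.
#' The factor is the median over standards of measured / expected, averaged
#' over the condition's replicate samples.
#'
#' @param result an [AbsoluteQuantResult-class] with `fmolMS` filled.
#' @param params an [ExperimentalParams-class].
#' @param standards an [EnrichmentStandards-class] (accession -> stock
#'   fmol/uL).
#' @param condition the condition to compute the factor for; must have
#'   `Enrichment = TRUE` and the standard settings in its parameters row.
#' @return an [EnrichmentFactor-class] with basis `"spiked_standards"`.
#'   Standards absent from the result are skipped with a warning; none
#'   usable is an error.
#' @export
computeEnrichment <- function(result, params, standards, condition) {
  stopifnot(is(result, "AbsoluteQuantResult"), is(params, "ExperimentalParams"),
            is(standards, "EnrichmentStandards"))
  row <- .paramsRow(params, condition)
  if (!isTRUE(row$enrichment))
    stop("condition '", condition, "' is not marked as enriched", call. = FALSE)
  if (is.na(row$stdDilution) || is.na(row$stdVolumeUl))
    stop("condition '", condition,
         "' has no StdDilution/StdVolume; use srmEnrichment() for SRM-derived factors",
         call. = FALSE)
  q <- result@quant
  samples <- .conditionSamples(unique(q$sample), condition)
  totalUg <- row$sampleVolumeUl * row$proteinConcUgPerUl
  expectedShare <- (standards@stocks / row$stdDilution) * row$stdVolumeUl *
    row$amountMSUg / totalUg

  perSample <- numeric(0)
  usable <- character(0)
  for (s in samples) {
    qs <- q[q$sample == s, ]
    firstAcc <- sub(";.*$", "", qs$proteinId)
    meas <- qs$fmolMS[match(names(standards@stocks), firstAcc)]
    ok <- is.finite(meas)
    if (!all(ok))
      warning("standards not quantified in sample '", s, "': ",
              paste(names(standards@stocks)[!ok], collapse = ", "))
    if (!any(ok)) next
    perSample <- c(perSample, stats::median(meas[ok] / expectedShare[ok]))
    usable <- union(usable, names(standards@stocks)[ok])
  }
  if (!length(perSample))
    stop("no usable enrichment standard for condition '", condition, "'",
         call. = FALSE)
  new("EnrichmentFactor", condition = condition, factor = mean(perSample),
      nStandards = length(usable), basis = "spiked_standards")
}

#' Enrichment factor from externally supplied SRM amounts
#'
#' When the enrichment of a fraction was measured by targeted proteomics
#' (SRM), the parameters table lists the measured accessions and their
#' native fmol (per injection). The factor is the median over listed
#' proteins of calibrated fmolMS / supplied fmol, averaged over the
#' condition's replicates.
#'
#' @inheritParams computeEnrichment
#' @return an [EnrichmentFactor-class] with basis `"srm_supplied"`. Listed
#'   accessions absent from the result are skipped with a warning; none
#'   usable is an error.
#' @export
srmEnrichment <- function(result, params, condition) {
  stopifnot(is(result, "AbsoluteQuantResult"), is(params, "ExperimentalParams"))
  row <- .paramsRow(params, condition)
  srm <- row$proteinSRM[[1L]]
  fm <- row$fmolSRM[[1L]]
  if (!length(srm))
    stop("condition '", condition, "' lists no SRM proteins", call. = FALSE)
  q <- result@quant
  samples <- .conditionSamples(unique(q$sample), condition)
  perSample <- numeric(0)
  usable <- character(0)
  for (s in samples) {
    qs <- q[q$sample == s, ]
    firstAcc <- sub(";.*$", "", qs$proteinId)
    meas <- qs$fmolMS[match(srm, firstAcc)]
    ok <- is.finite(meas)
    if (!all(ok))
      warning("SRM proteins not quantified in sample '", s, "': ",
              paste(srm[!ok], collapse = ", "))
    if (!any(ok)) next
    perSample <- c(perSample, stats::median(meas[ok] / fm[ok]))
    usable <- union(usable, srm[ok])
  }
  if (!length(perSample))
    stop("no usable SRM protein for condition '", condition, "'", call. = FALSE)
  new("EnrichmentFactor", condition = condition, factor = mean(perSample),
      nStandards = length(usable), basis = "srm_supplied")
}

#' Convert MS-scale fmol to absolute abundances
#'
#' Fills the three absolute units for every protein and sample:
#' \describe{
#'   \item{fmolTotal}{`fmolMS x total protein (ug) / AmountMS`, where total
#'     protein = SampleVolume x ProteinConcentration — the amount in the
#'     whole digested extract. Divided by the enrichment factor where the
#'     condition was enriched or concentrated.}
#'   \item{ngPerUg}{`fmolMS x MW(kDa) x 1e-3 / AmountMS` — the protein's
#'     mass share per ug of measured proteome (fmol x kDa x 1e-3 = ng).}
#'   \item{moleculesPerCell}{`fmolTotal x 1e-15 x N_A / cells`, with
#'     Avogadro's number N_A and cells = CellsPerML x culture volume in mL;
#'     the digested extract is taken to represent the whole harvested
#'     biomass.}
#' }
#'
#' @param result an [AbsoluteQuantResult-class] with `fmolMS` filled.
#' @param params an [ExperimentalParams-class]; every condition matched by
#'   the result's samples needs a row, otherwise an error.
#' @param factors optional list of [EnrichmentFactor-class] objects; a
#'   condition with `Enrichment = TRUE` and a supplied factor has
#'   `fmolTotal` (and hence molecules per cell) divided by it and its
#'   `enrichmentCorrected` flag set.
#' @param molWeights optional named numeric vector of molecular weights in
#'   kDa, names matching protein IDs (e.g. [molWeights()] of the report,
#'   or [molWeightsFromFasta()]). Missing weights leave `ngPerUg` unset
#'   with one warning.
#' @return the [AbsoluteQuantResult-class] with `condition`, `fmolTotal`,
#'   `ngPerUg`, `moleculesPerCell` and `enrichmentCorrected` columns filled.
#' @export
toAbsolute <- function(result, params, factors = NULL, molWeights = NULL) {
  stopifnot(is(result, "AbsoluteQuantResult"), is(params, "ExperimentalParams"))
  if (is(factors, "EnrichmentFactor")) factors <- list(factors)
  factorMap <- list()
  for (f in factors) factorMap[[f@condition]] <- f@factor

  q <- result@quant
  conds <- params@params$condition
  # longest matching condition first, so Cond10 is not claimed by Cond1
  condFor <- function(s) {
    hit <- conds[s == conds | startsWith(s, conds)]
    if (!length(hit))
      stop("no parameters row matches sample '", s, "'", call. = FALSE)
    hit[which.max(nchar(hit))]
  }
  sampleConds <- vapply(unique(q$sample), condFor, character(1))
  q$condition <- unname(sampleConds[q$sample])

  mw <- if (is.null(molWeights)) numeric(0) else molWeights
  q$fmolTotal <- NA_real_
  q$ngPerUg <- NA_real_
  q$moleculesPerCell <- NA_real_
  q$enrichmentCorrected <- FALSE

  mwMissing <- character(0)
  for (cond in unique(q$condition)) {
    row <- .paramsRow(params, cond)
    sel <- q$condition == cond
    totalUg <- row$sampleVolumeUl * row$proteinConcUgPerUl
    fmolTotal <- q$fmolMS[sel] * totalUg / row$amountMSUg
    corrected <- FALSE
    if (isTRUE(row$enrichment) && !is.null(factorMap[[cond]])) {
      fmolTotal <- fmolTotal / factorMap[[cond]]
      corrected <- TRUE
    }
    q$fmolTotal[sel] <- fmolTotal
    q$enrichmentCorrected[sel] <- corrected

    w <- mw[q$proteinId[sel]]
    mwMissing <- union(mwMissing, q$proteinId[sel][is.na(w)])
    q$ngPerUg[sel] <- q$fmolMS[sel] * w * 1e-3 / row$amountMSUg

    if (!is.na(row$cellsPerMl) && !is.na(row$totalCultureVolume)) {
      volMl <- if (params@cultureVolumeUnit == "uL")
        row$totalCultureVolume / 1000 else row$totalCultureVolume
      cellsTotal <- row$cellsPerMl * volMl
      q$moleculesPerCell[sel] <- fmolTotal * 1e-15 * .AVOGADRO / cellsTotal
    }
  }
  if (length(mwMissing) && length(mw))
    warning("no molecular weight for ", length(mwMissing),
            " protein(s); ngPerUg left unset for them")
  result@quant <- q
  result
}

# average residue masses (Da) for molecular weight from sequence
.AA_AVG_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886,
  C = 103.1388, E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411,
  I = 113.1594, L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766,
  P = 97.1167, S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760,
  V = 99.1326, U = 150.0388, O = 237.3018)
.WATER_MASS <- 18.01528

#' Molecular weights from a protein FASTA file
#'
#' Computes average molecular weights (kDa) from sequences, for reports
#' whose dialect carries no molecular-weight column. Accessions are taken
#' from the second `|`-delimited field of UniProt-style headers, else the
#' first whitespace-delimited token.
#'
#' @param path path to an uncompressed protein FASTA file.
#' @return named numeric vector, accession -> average MW in kDa.
#' @export
molWeightsFromFasta <- function(path) {
  if (!file.exists(path)) stop("cannot read FASTA: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- cumsum(hdr)
  acc <- vapply(sub("^>", "", lines[hdr]), function(h) {
    parts <- strsplit(h, "|", fixed = TRUE)[[1L]]
    if (length(parts) >= 2L) parts[2L] else strsplit(h, "\\s+")[[1L]][1L]
  }, character(1), USE.NAMES = FALSE)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste0, character(1),
                 collapse = "")
  mw <- vapply(seqs, function(s) {
    aa <- strsplit(toupper(s), "")[[1L]]
    sum(.AA_AVG_MASS[aa], na.rm = TRUE) + .WATER_MASS
  }, numeric(1), USE.NAMES = FALSE)
  stats::setNames(mw / 1000, acc)
}
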
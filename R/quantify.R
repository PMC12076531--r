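# Anchor-protein calibration: ordinary least squares of log10(intensity) on
# log10(spiked fmol), inverted to estimate fmol for every protein, and a
# consultant that ranks (intensity method, normalization) candidates by how
# well the anchors fit.

.readTwoColumnTable <- function(path, what) {
  if (!file.exists(path)) stop("cannot read ", what, " table: ", path,
                               call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1L]]
  hasHeader <- length(first) >= 2L &&
    is.na(suppressWarnings(as.numeric(first[2L])))
  df <- utils::read.table(path, sep = sep, header = hasHeader,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2L)
    stop(what, " table needs two columns (accession, value): ", path,
         call. = FALSE)
  acc <- as.character(df[[1L]])
  val <- suppressWarnings(as.numeric(df[[2L]]))
  bad <- which(!is.finite(val) | val <= 0)
  if (length(bad))
    stop(sprintf("%s table '%s': non-positive or non-numeric value in row %d ('%s')",
                 what, path, bad[1L], acc[bad[1L]]), call. = FALSE)
  if (anyDuplicated(acc))
    stop(what, " table has duplicate accession: ",
         acc[duplicated(acc)][1L], call. = FALSE)
  stats::setNames(val, acc)
}

#' Read an anchor-protein table
#'
#' Reads a two-column table mapping anchor-protein accessions to the amount
#' spiked at the MS-injection level (fmol), e.g. a UPS2 standard sheet
#' exported as text. TSV and CSV are accepted, with or without a header
#' row; spreadsheets should be exported to TSV first.
#'
#' @param path path to the table.
#' @return an [AnchorSet-class]. Duplicate accessions and non-positive
#'   amounts are errors.
#' @export
readAnchors <- function(path) {
  new("AnchorSet", amounts = .readTwoColumnTable(path, "anchor"),
      sourcePath = as.character(path))
}

#' Read an enrichment-standards table
#'
#' Two columns: accession, stock concentration of the enrichment standard
#' in fmol/uL.
#'
#' @param path path to a TSV/CSV table.
#' @return an [EnrichmentStandards-class].
#' @export
readEnrichmentStandards <- function(path) {
  new("EnrichmentStandards",
      stocks = .readTwoColumnTable(path, "enrichment-standard"),
      sourcePath = as.character(path))
}

# Match anchors to report rows on the first accession of each protein
# group. Anchors hit by >= 2 groups are ambiguous and dropped.
.matchAnchors <- function(report, anchors) {
  acc <- firstAccessions(report)
  rows <- match(names(anchors@amounts), acc)
  multi <- vapply(names(anchors@amounts), function(a) sum(acc == a) > 1L,
                  logical(1))
  if (any(multi)) {
    warning("anchors matched by multiple protein groups dropped: ",
            paste(names(anchors@amounts)[multi], collapse = ", "))
    rows[multi] <- NA_integer_
  }
  rows
}

#' Fit the anchor calibration curve
#'
#' Ordinary least squares of log10(measured intensity) on log10(spiked
#' fmol) over the anchor proteins found in one sample. Anchors missing in
#' the sample, matched by more than one protein group, or (by default)
#' carrying an imputed intensity are excluded and listed in the model.
#' With `sample = NULL` and more than one sample, all samples' anchor
#' points are pooled into a single fit.
#'
#' @param report a [QuantReport-class].
#' @param anchors an [AnchorSet-class].
#' @param method intensity method; default first method of the report.
#' @param sample sample label to fit, or `NULL` to pool all samples.
#' @param includeImputed logical; imputed anchor intensities are not
#'   measurements and are excluded from the fit unless `TRUE`.
#' @return a [CalibrationModel-class]. Fewer than 3 usable anchors, or zero
#'   variance of log10(fmol) among them, is an error.
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("Protein IDs\tMajority protein IDs\tiBAQ S1",
#'              "A\tA\t1e4", "B\tB\t1e5", "C\tC\t1e6"), tf)
#' rep <- readReport(tf)
#' anchors <- new("AnchorSet", amounts = c(A = 1, B = 10, C = 100),
#'                sourcePath = "inline")
#' fitAnchors(rep, anchors, "iBAQ", "S1")   # slope 1, intercept 4, R^2 1
#'
#' @export
fitAnchors <- function(report, anchors, method = NULL, sample = NULL,
                       includeImputed = FALSE) {
  stopifnot(is(report, "QuantReport"), is(anchors, "AnchorSet"))
  method <- .checkMethod(report, method)
  mat <- report@intensities[[method]]
  mask <- imputedMask(report, method)
  samples <- if (is.null(sample)) colnames(mat) else sample
  if (!all(samples %in% colnames(mat)))
    stop("unknown sample(s): ",
         paste(setdiff(samples, colnames(mat)), collapse = ", "), call. = FALSE)
  rows <- .matchAnchors(report, anchors)

  xs <- ys <- numeric(0)
  used <- character(0)
  for (s in samples) {
    I <- mat[rows, s]
    imp <- mask[rows, s]
    ok <- !is.na(rows) & is.finite(I)
    if (!includeImputed) ok <- ok & !(imp %in% TRUE)
    xs <- c(xs, log10(anchors@amounts[ok]))
    ys <- c(ys, log10(I[ok]))
    used <- union(used, names(anchors@amounts)[ok])
  }
  excluded <- setdiff(names(anchors@amounts), used)
  if (length(xs) < 3L)
    stop(sprintf("insufficient anchors: %d matched with finite intensity in %s (need >= 3)",
                 length(xs), paste(samples, collapse = "+")), call. = FALSE)
  if (stats::sd(xs) == 0)
    stop("zero variance in log10(fmol) of the matched anchors", call. = FALSE)

  fit <- stats::lm(ys ~ xs)
  tss <- sum((ys - mean(ys))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::residuals(fit)^2) / tss
  new("CalibrationModel",
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      rSquared = min(max(r2, 0), 1),
      nAnchorsUsed = length(xs),
      method = method, normalization = "unspecified",
      sampleScope = if (length(samples) > 1L) "pooled" else "per-sample",
      sample = samples, anchorsExcluded = excluded)
}

#' Estimate fmol for every protein by inverting the calibration
#'
#' For every protein with finite intensity in the model's sample(s),
#' `fmolMS = 10^((log10(I) - intercept) / slope)`: the amount (fmol) of the
#' protein in the injected sample. Provenance records whether the
#' underlying intensity was observed or imputed.
#'
#' @param report a [QuantReport-class].
#' @param model a [CalibrationModel-class] (or a list of per-sample models,
#'   as returned by [quantifyReport()]'s internals).
#' @return an [AbsoluteQuantResult-class] with `fmolMS` filled.
#' @export
estimateAmounts <- function(report, model) {
  stopifnot(is(report, "QuantReport"))
  models <- if (is(model, "CalibrationModel")) list(model) else model
  stopifnot(all(vapply(models, is, logical(1), "CalibrationModel")))
  mat <- report@intensities[[models[[1L]]@method]]
  mask <- imputedMask(report, models[[1L]]@method)
  out <- list()
  for (m in models) {
    for (s in m@sample) {
      I <- mat[, s]
      ok <- is.finite(I)
      out[[length(out) + 1L]] <- data.frame(
        proteinId = proteinIds(report)[ok],
        sample = s,
        intensity = I[ok],
        fmolMS = 10^((log10(I[ok]) - m@intercept) / m@slope),
        provenance = ifelse(mask[ok, s], "imputed", "observed"),
        stringsAsFactors = FALSE
      )
    }
  }
  quant <- do.call(rbind, out)
  rownames(quant) <- NULL
  new("AbsoluteQuantResult", quant = quant, models = models,
      method = models[[1L]]@method)
}

#' Calibrate and quantify every sample of a report
#'
#' Convenience wrapper: fits one calibration per sample (or a single pooled
#' model) and inverts it for all proteins.
#'
#' @inheritParams fitAnchors
#' @param scope `"per-sample"` (default) fits one model per sample —
#'   spike-ins are added per injection, so this absorbs run-to-run response
#'   drift; `"pooled"` fits all samples' anchor points jointly.
#' @return an [AbsoluteQuantResult-class].
#' @export
quantifyReport <- function(report, anchors, method = NULL,
                           scope = c("per-sample", "pooled"),
                           includeImputed = FALSE) {
  scope <- match.arg(scope)
  method <- .checkMethod(report, method)
  if (scope == "pooled") {
    model <- fitAnchors(report, anchors, method, sample = NULL,
                        includeImputed = includeImputed)
    return(estimateAmounts(report, model))
  }
  models <- lapply(sampleLabels(report, method), function(s)
    fitAnchors(report, anchors, method, s, includeImputed = includeImputed))
  estimateAmounts(report, models)
}

#' Rank intensity methods and normalizations by anchor fit
#'
#' For each (intensity method, normalization) candidate the raw report is
#' normalized, anchors are fitted per sample, and candidates are ranked by
#' the mean R-squared across samples, descending. Ties break towards the
#' larger mean number of anchors used, then lexicographically by method
#' and normalization name, so the recommendation is deterministic.
#'
#' @param report a raw (unnormalized) [QuantReport-class].
#' @param anchors an [AnchorSet-class].
#' @param candidateMethods intensity methods to try; default all detected.
#' @param candidateNormalizations normalizations to try; default all four.
#' @return a data.frame ranked best-first with columns `method`,
#'   `normalization`, `meanRSquared`, `meanAnchorsUsed`, `nSamplesFitted`.
#'   The top row is the recommendation. All candidates failing anchor
#'   matching is an error.
#' @export
consult <- function(report, anchors,
                    candidateMethods = intensityMethods(report),
                    candidateNormalizations = c("none", "median", "quantile",
                                                "total_sum")) {
  stopifnot(is(report, "QuantReport"), is(anchors, "AnchorSet"))
  rows <- list()
  for (m in candidateMethods) {
    for (nrm in candidateNormalizations) {
      fits <- NULL
      suppressWarnings(try(silent = TRUE, {
        normed <- normalizeIntensities(report, nrm)
        fits <- lapply(sampleLabels(normed, m), function(s)
          tryCatch(fitAnchors(normed, anchors, m, s), error = function(e) NULL))
        fits <- Filter(Negate(is.null), fits)
      }))
      if (is.null(fits) || !length(fits)) next
      rows[[length(rows) + 1L]] <- data.frame(
        method = m, normalization = nrm,
        meanRSquared = mean(vapply(fits, slot, numeric(1), "rSquared")),
        meanAnchorsUsed = mean(vapply(fits, function(f)
          as.numeric(f@nAnchorsUsed), numeric(1))),
        nSamplesFitted = length(fits),
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows))
    stop("no candidate could be fitted: anchors match too few proteins",
         call. = FALSE)
  tab <- do.call(rbind, rows)
  ord <- order(-tab$meanRSquared, -tab$meanAnchorsUsed, tab$method,
               tab$normalization)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
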
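# Routine label-free preprocessing: contaminant removal, replicate-group
# inference from sample names, validity filtering, normalization and
# Gaussian-downshift imputation. All normalization and imputation happens in
# log2 space internally; the QuantReport keeps raw-scale intensities
# throughout so calibration (log10 space) sees one consistent representation.

.subsetReport <- function(report, keep) {
  report@rowData <- report@rowData[keep, , drop = FALSE]
  rownames(report@rowData) <- NULL
  report@intensities <- lapply(report@intensities, function(m)
    m[keep, , drop = FALSE])
  if (length(report@imputed))
    report@imputed <- lapply(report@imputed, function(m) m[keep, , drop = FALSE])
  report
}

#' Remove flagged protein groups
#'
#' Drops rows flagged as potential contaminant, reverse (decoy) hit, or
#' identified only by a modification site.
#'
#' @param report a [QuantReport-class].
#' @return the report without flagged rows.
#' @export
removeFlagged <- function(report) {
  stopifnot(is(report, "QuantReport"))
  rd <- report@rowData
  .subsetReport(report, !(rd$isContaminant | rd$isReverse | rd$isSiteOnly))
}

# Tokenize a sample label: split on the separators _ - . and space, on
# letter/digit boundaries, and on lower-to-upper case changes.
.tokenizeLabel <- function(label) {
  x <- gsub("([a-z])([A-Z])", "\\1\r\\2", label)
  x <- gsub("([A-Za-z])([0-9])", "\\1\r\\2", x)
  x <- gsub("([0-9])([A-Za-z])", "\\1\r\\2", x)
  toks <- strsplit(x, "[\r_. -]+")[[1L]]
  toks[nzchar(toks)]
}

.ROMAN <- c("I", "II", "III", "IV", "i", "ii", "iii", "iv")

.isReplicateToken <- function(tok) {
  grepl("^[0-9]+$", tok) || tok %in% .ROMAN ||
    (nchar(tok) == 1L && grepl("^[A-Za-z]$", tok))
}

# Strip the replicate token (and a trailing separator) from the original
# label to form the group label.
.baseLabel <- function(label, tok) {
  base <- sub(paste0("[_. -]?", tok, "$"), "", label)
  if (nzchar(base)) base else label
}

#' Infer replicate groups from sample names
#'
#' Partitions sample labels into replicate groups: labels that share all
#' name tokens except a trailing replicate token are grouped. Tokens are
#' delimited by any of `_`, `-`, `.`, space, a letter/digit boundary or a
#' lower-to-upper case change; a trailing token counts as a replicate token
#' if it is an integer, a roman numeral up to IV, or a single letter. Labels
#' with no replicate partner stay as singleton groups under their full name.
#' The result is deterministic and invariant to the input order.
#'
#' @param sampleLabels character vector of sample names (>= 1).
#' @return a [SampleGrouping-class].
#'
#' @examples
#' groupList(inferGroups(c("Ctrl_1", "Ctrl_2", "Stress_1", "Stress_2")))
#'
#' @export
inferGroups <- function(sampleLabels) {
  stopifnot(is.character(sampleLabels), length(sampleLabels) >= 1L,
            !anyDuplicated(sampleLabels))
  labels <- sort(sampleLabels)
  keys <- character(length(labels))
  bases <- character(length(labels))
  for (i in seq_along(labels)) {
    toks <- .tokenizeLabel(labels[i])
    if (length(toks) >= 2L && .isReplicateToken(toks[length(toks)])) {
      keys[i] <- paste(toks[-length(toks)], collapse = "\r")
      bases[i] <- .baseLabel(labels[i], toks[length(toks)])
    } else {
      keys[i] <- NA_character_
    }
  }
  groups <- list()
  singleton <- FALSE
  groupNames <- character()
  groupMembers <- list()
  for (k in unique(keys[!is.na(keys)])) {
    idx <- which(!is.na(keys) & keys == k)
    if (length(idx) >= 2L) {
      groupNames <- c(groupNames, bases[idx[1L]])
      groupMembers <- c(groupMembers, list(labels[idx]))
    } else {
      keys[idx] <- NA_character_
    }
  }
  groups <- stats::setNames(groupMembers, make.unique(groupNames))
  for (i in which(is.na(keys))) {
    groups[[labels[i]]] <- labels[i]
    singleton <- TRUE
  }
  groups <- groups[order(names(groups))]
  new("SampleGrouping", groups = groups, singletonPolicyApplied = singleton)
}

#' Filter proteins on per-group validity
#'
#' Keeps a protein iff, in at least one replicate group, the fraction of
#' non-missing intensities reaches `minValidFraction`. Row order is
#' preserved; the filter is applied to all intensity methods of the report,
#' evaluating validity on the chosen method.
#'
#' @param report a [QuantReport-class].
#' @param grouping a [SampleGrouping-class] covering the method's samples.
#' @param method intensity method to evaluate; default first method.
#' @param minValidFraction required fraction of observed values within a
#'   group, in (0, 1]; default 2/3.
#' @return the filtered report (a warning, not an error, if nothing survives).
#' @export
filterValid <- function(report, grouping, method = NULL,
                        minValidFraction = 2 / 3) {
  stopifnot(is(report, "QuantReport"), is(grouping, "SampleGrouping"),
            minValidFraction > 0, minValidFraction <= 1)
  method <- .checkMethod(report, method)
  mat <- report@intensities[[method]]
  miss <- setdiff(colnames(mat), unlist(grouping@groups))
  if (length(miss))
    stop("grouping does not cover samples: ", paste(miss, collapse = ", "),
         call. = FALSE)
  keep <- rep(FALSE, nrow(mat))
  for (g in grouping@groups) {
    g <- intersect(g, colnames(mat))
    if (!length(g)) next
    frac <- rowMeans(!is.na(mat[, g, drop = FALSE]))
    keep <- keep | (frac >= minValidFraction - 1e-12)
  }
  if (!any(keep)) warning("no protein passes the validity filter")
  .subsetReport(report, keep)
}

.normalizeMatrix <- function(mat, normalization) {
  switch(normalization,
    none = mat,
    median = {
      lg <- log2(mat)
      meds <- apply(lg, 2L, stats::median, na.rm = TRUE)
      ok <- colSums(is.finite(lg)) >= 2L
      if (any(!ok))
        warning("samples with < 2 finite values left unnormalized: ",
                paste(colnames(mat)[!ok], collapse = ", "))
      target <- stats::median(meds[ok])
      shift <- ifelse(ok, target - meds, 0)
      2^sweep(lg, 2L, -shift)
    },
    quantile = {
      lg <- log2(mat)
      ok <- colSums(is.finite(lg)) >= 2L
      if (any(!ok))
        warning("samples with < 2 finite values left unnormalized: ",
                paste(colnames(mat)[!ok], collapse = ", "))
      out <- lg
      out[, ok] <- limma::normalizeQuantiles(lg[, ok, drop = FALSE])
      2^out
    },
    total_sum = {
      tot <- colSums(mat, na.rm = TRUE)
      ok <- colSums(!is.na(mat)) >= 2L & tot > 0
      if (any(!ok))
        warning("samples with < 2 finite values left unnormalized: ",
                paste(colnames(mat)[!ok], collapse = ", "))
      scale <- ifelse(ok, mean(tot[ok]) / tot, 1)
      sweep(mat, 2L, scale, `*`)
    },
    stop("unknown normalization: ", normalization, call. = FALSE)
  )
}

#' Normalize intensities across samples
#'
#' Applies one of three between-sample normalizations to every intensity
#' method of the report. `median` and `quantile` operate on log2
#' intensities (median: shift each sample so its median equals the global
#' median of sample medians; quantile: replace each value by the mean of
#' its quantile across samples, ties averaged, via
#' [limma::normalizeQuantiles()]); `total_sum` divides each raw value by
#' its sample total and rescales by the mean total. Intensities are
#' returned on the raw scale in all cases. A sample with fewer than two
#' finite values is left unnormalized with a warning.
#'
#' @param report a [QuantReport-class].
#' @param normalization one of `"none"`, `"median"`, `"quantile"`,
#'   `"total_sum"`.
#' @return the normalized report.
#' @export
normalizeIntensities <- function(report,
                                 normalization = c("none", "median",
                                                   "quantile", "total_sum")) {
  stopifnot(is(report, "QuantReport"))
  normalization <- match.arg(normalization)
  if (normalization == "none") return(report)
  report@intensities <- lapply(report@intensities, .normalizeMatrix,
                               normalization = normalization)
  report
}

#' Impute left-censored missing values by Gaussian downshift
#'
#' Missing values of each sample are drawn from a normal distribution
#' down-shifted from that sample's observed log2-intensity distribution:
#' mean = sample mean - `downshiftSd` x sample sd, sd = `downshiftWidth` x
#' sample sd. This models the left-censoring of label-free data, where
#' proteins are missing mostly because they sit below the detection limit.
#' Observed values are never altered; imputed cells are marked and carried
#' through quantification as provenance. Defaults (1.8, 0.3) are the
#' field-standard downshift parameters for label-free proteomics.
#'
#' @param report a [QuantReport-class].
#' @param downshiftSd shift of the imputation distribution, in units of the
#'   sample's log2 sd; default 1.8.
#' @param downshiftWidth width of the imputation distribution, in units of
#'   the sample's log2 sd; default 0.3.
#' @param seed integer seed; every stochastic step in the package takes an
#'   explicit seed so runs are reproducible.
#' @return the report with missing values filled in (raw scale) and
#'   imputation marks set. Samples with fewer than 3 observed values are
#'   left unimputed with a warning.
#' @export
imputeMissing <- function(report, downshiftSd = 1.8, downshiftWidth = 0.3,
                          seed = 1L) {
  stopifnot(is(report, "QuantReport"), downshiftWidth > 0, downshiftSd >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  for (m in names(report@intensities)) {
    mat <- report@intensities[[m]]
    mask <- array(FALSE, dim = dim(mat), dimnames = dimnames(mat))
    if (!is.null(report@imputed[[m]])) mask <- report@imputed[[m]]
    for (j in seq_len(ncol(mat))) {
      obs <- log2(mat[, j])
      obs <- obs[is.finite(obs)]
      nMiss <- sum(is.na(mat[, j]))
      if (nMiss == 0L) next
      if (length(obs) < 3L) {
        warning(sprintf("sample '%s' (%s) has < 3 observed values; not imputed",
                        colnames(mat)[j], m))
        next
      }
      mu <- mean(obs) - downshiftSd * stats::sd(obs)
      sdev <- downshiftWidth * stats::sd(obs)
      idx <- which(is.na(mat[, j]))
      mat[idx, j] <- 2^stats::rnorm(nMiss, mu, sdev)
      mask[idx, j] <- TRUE
    }
    report@intensities[[m]] <- mat
    report@imputed[[m]] <- mask
  }
  report
}
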
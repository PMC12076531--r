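# Small in-code fixtures shared across test files.

writeTsvLines <- function(lines) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(lines, tf)
  tf
}

# Minimal MaxQuant-style report from a named list of sample -> intensities.
maxquantFixture <- function(ids, intensities, reverse = NULL, contam = NULL,
                            mw = NULL) {
  samples <- names(intensities)
  header <- c("Protein IDs", "Majority protein IDs",
              if (!is.null(mw)) "Mol. weight [kDa]",
              paste("iBAQ", samples), "Reverse", "Potential contaminant")
  rows <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], ids[i],
            if (!is.null(mw)) mw[i],
            vapply(samples, function(s) as.character(intensities[[s]][i]),
                   character(1)),
            if (!is.null(reverse) && reverse[i]) "+" else "",
            if (!is.null(contam) && contam[i]) "+" else ""),
          collapse = "\t")
  }, character(1))
  writeTsvLines(c(paste(header, collapse = "\t"), rows))
}

# An AbsoluteQuantResult built directly, bypassing calibration, for unit
# tests of the integration arithmetic.
quantResultFixture <- function(proteinId, sample, fmolMS,
                               provenance = "observed") {
  dummy <- new("CalibrationModel", slope = 1, intercept = 0, rSquared = 1,
               nAnchorsUsed = 3L, method = "iBAQ",
               normalization = "none", sampleScope = "per-sample",
               sample = unique(sample), anchorsExcluded = character(0))
  new("AbsoluteQuantResult",
      quant = data.frame(proteinId = proteinId, sample = sample,
                         intensity = fmolMS, fmolMS = fmolMS,
                         provenance = provenance, stringsAsFactors = FALSE),
      models = list(dummy), method = "iBAQ")
}

# Experimental-parameters table written from a data.frame of canonical
# columns.
paramsFixture <- function(df) {
  tf <- tempfile(fileext = ".tsv")
  write.table(df, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  tf
}

samePartition <- function(a, b) {
  canon <- function(p) {
    p <- lapply(p, sort)
    unname(p[order(vapply(p, `[`, character(1), 1L))])
  }
  identical(canon(a), canon(b))
}
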
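# Reading protein-groups reports from the four supported search engines.
#
# Each engine writes a different protein-level table; the dialect decides
# which headers carry the protein identifier, flags and intensities. All
# dialects share the QuantReport representation afterwards.

.ID_PRECEDENCE <- c("Protein IDs", "Majority protein IDs", "Protein.Group",
                    "Protein ID", "PG.ProteinGroups")

# Known intensity-method prefixes, longest first so "LFQ intensity A1" is
# never claimed by the bare "Intensity" method.
.METHOD_PREFIXES <- c("MaxLFQ Intensity", "LFQ intensity", "PG.MaxLFQ",
                      "PG.Quantity", "iBAQ", "Top3", "Intensity")

.detectEngine <- function(headers) {
  if ("Majority protein IDs" %in% headers) return("maxquant")
  if (any(c("Protein Probability", "Combined Total Peptides") %in% headers))
    return("msfragger")
  if ("Protein.Group" %in% headers) return("diann")
  if (any(grepl("PG\\.Quantity", headers))) return("spectronaut")
  stop("cannot identify the report dialect from its headers: ",
       paste(headers, collapse = ", "), call. = FALSE)
}

.pickIdColumn <- function(headers) {
  hit <- .ID_PRECEDENCE[.ID_PRECEDENCE %in% headers]
  if (length(hit)) hit[1L] else headers[1L]
}

.asNumericColumn <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  suppressWarnings(as.numeric(x))
}

# prefix-style detection (MaxQuant and friends): "iBAQ A1", "LFQ intensity A1";
# a column equal to the bare method name is MaxQuant's experiment-summed
# column and is not a sample.
.detectPrefixMethods <- function(headers) {
  out <- list()
  claimed <- character()
  for (m in .METHOD_PREFIXES) {
    cand <- headers[startsWith(headers, paste0(m, " ")) & !headers %in% claimed]
    if (length(cand)) {
      out[[m]] <- list(columns = cand,
                       samples = substring(cand, nchar(m) + 2L))
      claimed <- c(claimed, cand)
    }
  }
  out
}

# suffix-style detection (MSFragger combined_protein): "<sample> Intensity",
# "<sample> MaxLFQ Intensity". "Combined ..." columns are totals, not samples.
.detectSuffixMethods <- function(headers) {
  out <- list()
  claimed <- character()
  for (m in c("MaxLFQ Intensity", "Intensity")) {
    suf <- paste0(" ", m)
    cand <- headers[endsWith(headers, suf) & !headers %in% claimed &
                      !startsWith(headers, "Combined")]
    samples <- substring(cand, 1L, nchar(cand) - nchar(suf))
    keep <- nzchar(samples)
    if (any(keep)) {
      out[[m]] <- list(columns = cand[keep], samples = samples[keep])
      claimed <- c(claimed, cand[keep])
    }
  }
  out
}

# Spectronaut pivot report: "[1] RunA.PG.Quantity" -> method "PG.Quantity",
# sample "RunA".
.detectSpectronautMethods <- function(headers) {
  out <- list()
  for (m in c("PG.Quantity", "PG.MaxLFQ")) {
    pat <- paste0("^(\\[[0-9]+\\] )?(.*)\\.", gsub(".", "\\.", m, fixed = TRUE), "$")
    cand <- headers[grepl(pat, headers)]
    if (length(cand))
      out[[m]] <- list(columns = cand, samples = sub(pat, "\\2", cand))
  }
  out
}

.DIALECT_META <- c(.ID_PRECEDENCE, "Protein", "Protein.Ids", "Protein.Names",
  "Genes", "Gene", "Gene names", "First.Protein.Description", "Description",
  "Fasta headers", "Protein Probability", "Combined Total Peptides",
  "Mol. weight [kDa]", "PG.Genes", "PG.MolecularWeight", "Reverse",
  "Potential contaminant", "Contaminant", "Only identified by site",
  "Indistinguishable Proteins", "Organism", "Protein Length",
  "Entry Name", "Peptides", "Sequence coverage [%]")

# DIA-NN pg_matrix fallback: every non-metadata column that parses as
# numeric is one run of a single method.
.detectBareRunMethods <- function(df) {
  headers <- names(df)
  cand <- setdiff(headers, .DIALECT_META)
  isnum <- vapply(cand, function(h) {
    v <- .asNumericColumn(df[[h]])
    any(is.finite(v)) || all(is.na(df[[h]]) | df[[h]] == "")
  }, logical(1))
  cand <- cand[isnum]
  if (!length(cand)) return(list())
  list(Intensity = list(columns = cand, samples = cand))
}

.plusFlag <- function(df, col) {
  if (!col %in% names(df)) return(rep(FALSE, nrow(df)))
  v <- df[[col]]
  !is.na(v) & (v == "+" | v == "TRUE" | v == "True" | v == "1")
}

.firstExisting <- function(df, cols) {
  hit <- cols[cols %in% names(df)]
  if (length(hit)) df[[hit[1L]]] else rep(NA_character_, nrow(df))
}

#' Read a protein-groups report
#'
#' Imports the protein-level output table of a proteomics search engine and
#' returns a [QuantReport-class]: one row per protein group, one intensity
#' matrix per detected quantification method (iBAQ, LFQ intensity,
#' PG.Quantity, ...). Zero intensities are coerced to `NA` — label-free
#' engines write 0 for "not quantified", and downstream log transforms
#' require strictly positive values.
#'
#' @param path path to a tab-separated protein-groups report
#'   (`proteinGroups.txt`, `combined_protein.tsv`, a DIA-NN `pg_matrix`
#'   report, or a Spectronaut pivot report).
#' @param engine one of `"auto"`, `"maxquant"`, `"msfragger"`, `"diann"`,
#'   `"spectronaut"`. With `"auto"` the dialect is resolved from header
#'   signatures: "Majority protein IDs" marks MaxQuant, "Protein
#'   Probability"/"Combined Total Peptides" MSFragger, "Protein.Group"
#'   DIA-NN, and a "PG.Quantity" header Spectronaut.
#'
#' @return a [QuantReport-class] with contaminant/reverse/site-only flags
#'   populated where the dialect defines them (`FALSE` otherwise).
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("Protein IDs\tMajority protein IDs\tiBAQ A1\tiBAQ A2",
#'              "P1\tP1\t100\t110", "P2\tP2\t0\t90"), tf)
#' rep <- readReport(tf)
#' intensityMatrix(rep, "iBAQ")   # P2/A1 is NA: zero means not quantified
#'
#' @seealso [inspectReport()] for the detected method catalog.
#' @export
readReport <- function(path,
                       engine = c("auto", "maxquant", "msfragger", "diann",
                                  "spectronaut")) {
  engine <- match.arg(engine)
  if (!file.exists(path)) stop("cannot read report: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  if (nrow(df) == 0L) stop("report '", path, "' has no data rows", call. = FALSE)
  headers <- names(df)
  if (engine == "auto") engine <- .detectEngine(headers)

  methods <- switch(engine,
    maxquant = .detectPrefixMethods(headers),
    msfragger = .detectSuffixMethods(headers),
    spectronaut = .detectSpectronautMethods(headers),
    diann = .detectBareRunMethods(df)
  )
  if (!length(methods)) methods <- .detectBareRunMethods(df)

  if (!length(methods))
    stop("no intensity columns recognised; headers seen: ",
         paste(headers, collapse = ", "), call. = FALSE)
  idColumn <- .pickIdColumn(headers)

  proteinId <- as.character(df[[idColumn]])
  if (any(is.na(proteinId) | !nzchar(proteinId))) {
    drop <- is.na(proteinId) | !nzchar(proteinId)
    warning(sum(drop), " rows without a protein identifier dropped")
    df <- df[!drop, , drop = FALSE]
    proteinId <- proteinId[!drop]
  }

  mw <- .asNumericColumn(.firstExisting(df, c("Mol. weight [kDa]",
                                              "PG.MolecularWeight")))
  gene <- as.character(.firstExisting(df, c("Gene names", "Gene", "Genes",
                                            "PG.Genes")))
  rowData <- data.frame(
    proteinId = proteinId,
    geneName = gene,
    molWeightKDa = mw,
    isContaminant = .plusFlag(df, "Potential contaminant") |
      .plusFlag(df, "Contaminant") | grepl("^CON__|^contam_", proteinId),
    isReverse = .plusFlag(df, "Reverse") | grepl("^REV__|^rev_", proteinId),
    isSiteOnly = .plusFlag(df, "Only identified by site"),
    stringsAsFactors = FALSE
  )

  intensities <- lapply(methods, function(m) {
    mat <- vapply(m$columns, function(col) .asNumericColumn(df[[col]]),
                  numeric(nrow(df)))
    mat <- matrix(mat, nrow = nrow(df),
                  dimnames = list(NULL, m$samples))
    mat[!is.na(mat) & mat <= 0] <- NA_real_   # 0 = not quantified
    mat
  })

  new("QuantReport", rowData = rowData, intensities = intensities,
      imputed = list(), engine = engine, idColumn = idColumn)
}

#' Catalog the intensity methods of a report
#'
#' Lists every intensity method detected at ingestion together with its
#' sample labels (method prefixes stripped), and the suggested
#' protein-identifier column. Suggested-ID precedence: "Protein IDs" >
#' "Majority protein IDs" > "Protein.Group" > "Protein ID" >
#' "PG.ProteinGroups" > first column of the report.
#'
#' @param report a [QuantReport-class].
#' @return an [IntensityCatalog-class].
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("Protein IDs\tMajority protein IDs\tiBAQ A1\tiBAQ A2",
#'              "P1\tP1\t100\t110"), tf)
#' inspectReport(readReport(tf))
#'
#' @export
inspectReport <- function(report) {
  stopifnot(is(report, "QuantReport"))
  new("IntensityCatalog",
      methods = lapply(report@intensities, colnames),
      suggestedIdColumn = report@idColumn)
}

setMethod("show", "IntensityCatalog", function(object) {
  cat("IntensityCatalog:\n")
  for (m in names(object@methods))
    cat(sprintf("  %s: %s\n", m, paste(object@methods[[m]], collapse = ", ")))
  cat("  suggested ID column:", object@suggestedIdColumn, "\n")
  invisible(NULL)
})

#' @rdname inspectReport
#' @param x an [IntensityCatalog-class].
#' @return `catalogMethods` returns the named list method -> sample labels;
#'   `suggestedIdColumn` the suggested identifier column.
#' @export
catalogMethods <- function(x) {
  stopifnot(is(x, "IntensityCatalog"))
  x@methods
}

#' @rdname inspectReport
#' @export
suggestedIdColumn <- function(x) {
  stopifnot(is(x, "IntensityCatalog"))
  x@suggestedIdColumn
}
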
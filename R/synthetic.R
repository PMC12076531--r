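# Ground-truth fixture generator: dialect-faithful protein-groups reports,
# anchor tables, parameter tables, enrichment scenarios and sample-name
# benchmarks, so every pipeline stage can be validated without external
# data. Intensities follow the calibration model the quantifier assumes,
#   log10(I) = a + b * log10(fmol) + N(0, sigma),
# i.e. multiplicative lognormal noise with sigma expressed as the sd of the
# log10 response. Missingness combines an intensity censoring threshold
# (left censoring, what Gaussian-downshift imputation models) with random
# Bernoulli dropout.

#' Specification of a synthetic quantification experiment
#'
#' @param nProteins number of (non-anchor) proteins.
#' @param nConditions,nReplicates experiment layout; samples are labelled
#'   `Cond<i>_<j>`.
#' @param amountRange dynamic range of true per-protein amounts (fmol at MS
#'   scale), drawn log-uniformly; default 1e-2 to 1e3.
#' @param anchorLevels amounts of the staggered-decade anchor design,
#'   emulating a two-component dynamic-range standard (UPS2-like): equal
#'   groups of anchors at each level. Default six decades, 0.05-5000 fmol.
#' @param nAnchors total anchors, split evenly over the levels; default 48.
#' @param intercept,slope response parameters a, b of
#'   `log10(I) = a + b log10(fmol)`.
#' @param noiseSigma sd of the log10 response noise (0 = noiseless).
#' @param censorThreshold intensities below this raw value are written as 0
#'   (left censoring); 0 disables.
#' @param dropoutRate probability that any intensity cell is dropped to 0.
#' @param nContaminants,nReverse planted contaminant / decoy rows.
#' @param enrichmentFactor planted fold enrichment for
#'   [makeEnrichmentScenario()]; `NA` elsewhere.
#' @param seed integer seed; generation is fully deterministic given the
#'   spec (byte-identical files on re-run).
#' @return a classed list of the settings, to pass to the generators.
#' @seealso [makeReport()], [makeEnrichmentScenario()]
#' @export
syntheticSpec <- function(nProteins = 200L, nConditions = 2L,
                          nReplicates = 3L, amountRange = c(1e-2, 1e3),
                          anchorLevels = c(0.05, 0.5, 5, 50, 500, 5000),
                          nAnchors = 48L, intercept = 5, slope = 1,
                          noiseSigma = 0, censorThreshold = 0,
                          dropoutRate = 0, nContaminants = 5L, nReverse = 3L,
                          enrichmentFactor = NA_real_, seed = 1L) {
  stopifnot(nProteins >= 1L, nConditions >= 1L, nReplicates >= 1L,
            length(amountRange) == 2L, all(amountRange > 0),
            noiseSigma >= 0, dropoutRate >= 0, dropoutRate < 1,
            nAnchors >= length(anchorLevels),
            max(anchorLevels) / min(anchorLevels) >= 100)  # >= 2 decades
  structure(list(
    nProteins = as.integer(nProteins), nConditions = as.integer(nConditions),
    nReplicates = as.integer(nReplicates), amountRange = amountRange,
    anchorLevels = anchorLevels, nAnchors = as.integer(nAnchors),
    intercept = intercept, slope = slope, noiseSigma = noiseSigma,
    censorThreshold = censorThreshold, dropoutRate = dropoutRate,
    nContaminants = as.integer(nContaminants), nReverse = as.integer(nReverse),
    enrichmentFactor = enrichmentFactor, seed = as.integer(seed)
  ), class = "syntheticSpec")
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  expr
}

.synthSamples <- function(spec) {
  unlist(lapply(seq_len(spec$nConditions), function(i)
    paste0("Cond", i, "_", seq_len(spec$nReplicates))))
}

.synthAnchorAmounts <- function(spec) {
  per <- spec$nAnchors %/% length(spec$anchorLevels)
  extra <- spec$nAnchors - per * length(spec$anchorLevels)
  counts <- rep(per, length(spec$anchorLevels)) +
    c(rep(1L, extra), rep(0L, length(spec$anchorLevels) - extra))
  amounts <- rep(spec$anchorLevels, counts)
  stats::setNames(amounts, sprintf("STD%03d", seq_along(amounts)))
}

.responseIntensity <- function(fmol, spec) {
  n <- length(fmol)
  eps <- if (spec$noiseSigma > 0) stats::rnorm(n, 0, spec$noiseSigma) else 0
  10^(spec$intercept + spec$slope * log10(fmol) + eps)
}

.applyMissingness <- function(mat, spec) {
  if (spec$censorThreshold > 0) mat[mat < spec$censorThreshold] <- 0
  if (spec$dropoutRate > 0) {
    drop <- stats::runif(length(mat)) < spec$dropoutRate
    mat[drop] <- 0
  }
  mat
}

.writeDialect <- function(df, ids, genes, mw, samples, flags, dialect, path) {
  fmtNum <- function(x) ifelse(x == 0, "0", format(x, digits = 12,
                                                   scientific = TRUE,
                                                   trim = TRUE))
  mat <- vapply(seq_along(samples), function(j) fmtNum(df[, j]),
                character(nrow(df)))
  mat <- matrix(mat, nrow = nrow(df))
  out <- switch(dialect,
    maxquant = {
      o <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
        "Protein IDs" = ids, "Majority protein IDs" = ids,
        "Gene names" = genes, "Mol. weight [kDa]" = mw)
      for (j in seq_along(samples)) o[[paste("iBAQ", samples[j])]] <- mat[, j]
      o[["iBAQ"]] <- fmtNum(rowSums(df))        # experiment-summed column
      o[["Reverse"]] <- ifelse(flags$rev, "+", "")
      o[["Potential contaminant"]] <- ifelse(flags$con, "+", "")
      o[["Only identified by site"]] <- ""
      o
    },
    msfragger = {
      o <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
        "Protein" = paste0("sp|", ids, "|", ids, "_SYN"),
        "Protein ID" = ids, "Gene" = genes,
        "Protein Probability" = rep("1.000", nrow(df)),
        "Combined Total Peptides" = rep("10", nrow(df)))
      for (j in seq_along(samples))
        o[[paste(samples[j], "Intensity")]] <- mat[, j]
      o
    },
    diann = {
      o <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
        "Protein.Group" = ids, "Protein.Ids" = ids,
        "Protein.Names" = paste0(ids, "_SYN"), "Genes" = genes,
        "First.Protein.Description" = paste("synthetic protein", ids))
      for (j in seq_along(samples)) {
        v <- mat[, j]
        v[df[, j] == 0] <- ""                   # pg_matrix leaves blanks
        o[[samples[j]]] <- v
      }
      o
    },
    spectronaut = {
      o <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
        "PG.ProteinGroups" = ids, "PG.Genes" = genes,
        "PG.MolecularWeight" = mw)
      for (j in seq_along(samples))
        o[[sprintf("[%d] %s.PG.Quantity", j, samples[j])]] <- mat[, j]
      o
    },
    stop("unknown dialect: ", dialect, call. = FALSE)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Generate a dialect-faithful protein-groups report with known truth
#'
#' Writes a synthetic protein-groups file in the chosen engine dialect
#' (headers, flag columns, planted contaminant/decoy rows), an anchor table
#' (accession, fmol), and a ground-truth table of the true per-protein fmol
#' at MS scale. Intensities follow the log-log response of the spec with
#' lognormal noise; values below the censoring threshold or hit by dropout
#' are written as 0 (blank for the DIA-NN dialect).
#'
#' @param spec a [syntheticSpec()].
#' @param dialect one of `"maxquant"`, `"msfragger"`, `"diann"`,
#'   `"spectronaut"`.
#' @param dir output directory (created if needed); default a fresh tempdir.
#' @return a list with `reportPath`, `anchorPath`, `truthPath`, the
#'   `truth` data.frame (proteinId, trueFmolMS), the named `anchorAmounts`
#'   vector and the `samples` labels.
#' @export
makeReport <- function(spec, dialect = c("maxquant", "msfragger", "diann",
                                         "spectronaut"),
                       dir = tempfile("synthreport")) {
  stopifnot(inherits(spec, "syntheticSpec"))
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .withSeed(spec$seed, {
    samples <- .synthSamples(spec)
    anchors <- .synthAnchorAmounts(spec)
    prot <- sprintf("SYN%04d", seq_len(spec$nProteins))
    fmol <- 10^stats::runif(spec$nProteins, log10(spec$amountRange[1]),
                            log10(spec$amountRange[2]))
    allIds <- c(prot, names(anchors))
    allFmol <- c(fmol, anchors)
    nAll <- length(allIds)

    intens <- vapply(seq_along(samples), function(j)
      .responseIntensity(allFmol, spec), numeric(nAll))
    intens <- .applyMissingness(matrix(intens, nrow = nAll), spec)

    conIds <- if (spec$nContaminants > 0)
      sprintf("CON__C%03d", seq_len(spec$nContaminants)) else character(0)
    revIds <- if (spec$nReverse > 0)
      sprintf("REV__R%03d", seq_len(spec$nReverse)) else character(0)
    nFlag <- length(conIds) + length(revIds)
    flagFmol <- 10^stats::runif(nFlag, log10(spec$amountRange[1]),
                                log10(spec$amountRange[2]))
    flagInt <- matrix(numeric(0), nrow = 0, ncol = length(samples))
    if (nFlag > 0) {
      flagInt <- vapply(seq_along(samples), function(j)
        .responseIntensity(flagFmol, spec), numeric(nFlag))
      flagInt <- matrix(flagInt, nrow = nFlag)
    }

    ids <- c(allIds, conIds, revIds)
    mat <- rbind(intens, flagInt)
    flags <- list(
      con = c(rep(FALSE, nAll), rep(TRUE, length(conIds)),
              rep(FALSE, length(revIds))),
      rev = c(rep(FALSE, nAll), rep(FALSE, length(conIds)),
              rep(TRUE, length(revIds)))
    )
    genes <- paste0("g", seq_along(ids))
    mw <- round(stats::runif(length(ids), 10, 150), 3)

    reportPath <- file.path(dir, switch(dialect,
      maxquant = "proteinGroups.txt", msfragger = "combined_protein.tsv",
      diann = "report.pg_matrix.tsv", spectronaut = "spectronaut_pivot.tsv"))
    .writeDialect(mat, ids, genes, mw, samples, flags, dialect, reportPath)

    anchorPath <- file.path(dir, "anchors.tsv")
    utils::write.table(
      data.frame(accession = names(anchors), fmol = anchors),
      anchorPath, sep = "\t", quote = FALSE, row.names = FALSE)

    truth <- data.frame(proteinId = allIds, trueFmolMS = unname(allFmol),
                        isAnchor = allIds %in% names(anchors),
                        stringsAsFactors = FALSE)
    truthPath <- file.path(dir, "ground_truth.tsv")
    utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    list(reportPath = reportPath, anchorPath = anchorPath,
         truthPath = truthPath, truth = truth, anchorAmounts = anchors,
         samples = samples)
  })
}

.BENCH_SEPARATORS <- c("_", "-", ".", " ", "")
.BENCH_REP_STYLES <- c("integer", "letter", "repN")

.randomWord <- function(len) paste(sample(letters, len, replace = TRUE),
                                   collapse = "")

# One label set: either a timepoint-like series (shared stem + index) or
# independent words, some carrying a digit suffix — the naming conventions
# replicate groups are written with in practice.
.makeLabelSet <- function() {
  nCond <- sample(2:6, 1L)
  nRep <- sample(2:5, 1L)
  sep <- sample(.BENCH_SEPARATORS, 1L)
  style <- sample(.BENCH_REP_STYLES, 1L)
  series <- stats::runif(1) < 0.3
  conds <- if (series) {
    paste0(.randomWord(sample(3:6, 1L)), seq_len(nCond) - 1L)
  } else {
    repeat {
      w <- vapply(seq_len(nCond), function(i) .randomWord(sample(3:8, 1L)),
                  character(1))
      suf <- ifelse(stats::runif(nCond) < 0.3,
                    as.character(sample(1:9, nCond, replace = TRUE)), "")
      out <- paste0(w, suf)
      if (!anyDuplicated(out)) break
    }
    out
  }
  reps <- switch(style,
    integer = as.character(seq_len(nRep)),
    letter = LETTERS[seq_len(nRep)],
    repN = paste0("rep", seq_len(nRep)))
  labels <- as.vector(t(outer(conds, reps, function(a, b) paste0(a, sep, b))))
  truth <- lapply(conds, function(cn) sort(paste0(cn, sep, reps)))
  list(labels = labels, truth = truth)
}

#' Generate a sample-naming benchmark for group inference
#'
#' Each set mimics one experiment's sample names: 2-6 condition tokens
#' (random words, 30% of sets a timepoint-like series sharing a stem, 30%
#' of plain words with a digit suffix), 2-5 replicates encoded as a suffix
#' integer, letter, or `repN`, and a separator drawn from `_`, `-`, `.`,
#' space, or none. The planted partition is recorded as truth.
#'
#' @param nSets number of label sets (>= 1).
#' @param seed integer seed; the benchmark is deterministic.
#' @return a list of `nSets` elements, each with `labels` (character
#'   vector) and `truth` (list of member vectors, the planted partition).
#' @seealso [scoreGroupingBenchmark()]
#' @export
makeGroupingBenchmark <- function(nSets = 500L, seed = 1L) {
  stopifnot(nSets >= 1L)
  .withSeed(seed, {
    sets <- vector("list", nSets)
    for (i in seq_len(nSets)) {
      repeat {
        s <- .makeLabelSet()
        if (!anyDuplicated(s$labels)) break
      }
      sets[[i]] <- s
    }
    sets
  })
}

.partitionsEqual <- function(a, b) {
  canon <- function(p) {
    p <- lapply(p, sort)
    p[order(vapply(p, `[`, character(1), 1L))]
  }
  identical(unname(canon(a)), unname(canon(b)))
}

#' Score group inference against a benchmark
#'
#' Runs [inferGroups()] on every label set and scores a set as correct iff
#' the inferred partition equals the planted one (group names ignored).
#'
#' @param benchmark output of [makeGroupingBenchmark()].
#' @return a list with `accuracy` (fraction correct), `n`, `nCorrect`, and
#'   the Wilson 95% confidence interval `ciLow`/`ciHigh`.
#' @export
scoreGroupingBenchmark <- function(benchmark) {
  correct <- vapply(benchmark, function(s) {
    got <- groupList(inferGroups(s$labels))
    .partitionsEqual(got, s$truth)
  }, logical(1))
  n <- length(correct)
  k <- sum(correct)
  z <- stats::qnorm(0.975)
  ph <- k / n
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  list(accuracy = ph, n = n, nCorrect = k,
       ciLow = max(0, ctr - hw), ciHigh = min(1, ctr + hw))
}

#' Generate an enrichment scenario with a planted factor
#'
#' Builds a two-condition experiment ("Base" and "Enriched"): the enriched
#' condition's protein amounts are the base amounts multiplied by
#' `spec$enrichmentFactor`, and three enrichment standards are spiked
#' consistently with the parameter table written alongside (stock
#' concentration, 1:10 dilution, 10 uL added). Anchors are included in
#' every sample so the full calibration pipeline can run.
#'
#' @param spec a [syntheticSpec()] with `enrichmentFactor` set.
#' @param dir output directory; default a fresh tempdir.
#' @return a list with `reportPath`, `anchorPath`, `standardsPath`,
#'   `paramsPath`, `truth` (data.frame of true base fmolMS per protein),
#'   `factor`, `standards` (named stock vector) and `samples`.
#' @export
makeEnrichmentScenario <- function(spec, dir = tempfile("synthenrich")) {
  stopifnot(inherits(spec, "syntheticSpec"), is.finite(spec$enrichmentFactor),
            spec$enrichmentFactor > 0)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- spec$enrichmentFactor
  .withSeed(spec$seed, {
    nRep <- spec$nReplicates
    samples <- c(paste0("Base_", seq_len(nRep)),
                 paste0("Enriched_", seq_len(nRep)))
    enriched <- grepl("^Enriched", samples)

    sampleVolumeUl <- 10; proteinConcUgPerUl <- 5; amountMSUg <- 5
    cellsPerMl <- 5e8; cultureVolumeUl <- 1000
    stdStocks <- stats::setNames(c(100, 200, 400), c("ENR01", "ENR02", "ENR03"))
    stdDilution <- 10; stdVolumeUl <- 10
    totalUg <- sampleVolumeUl * proteinConcUgPerUl
    expectedShare <- (stdStocks / stdDilution) * stdVolumeUl *
      amountMSUg / totalUg

    anchors <- .synthAnchorAmounts(spec)
    prot <- sprintf("SYN%04d", seq_len(spec$nProteins))
    baseFmol <- 10^stats::runif(spec$nProteins, log10(spec$amountRange[1]),
                                log10(spec$amountRange[2]))

    ids <- c(prot, names(anchors), names(stdStocks))
    mat <- matrix(0, nrow = length(ids), ncol = length(samples))
    for (j in seq_along(samples)) {
      fac <- if (enriched[j]) f else 1
      fmols <- c(baseFmol * fac, anchors,
                 if (enriched[j]) expectedShare * f else rep(NA, 3))
      I <- rep(0, length(ids))
      ok <- is.finite(fmols)
      I[ok] <- .responseIntensity(fmols[ok], spec)
      mat[, j] <- I
    }
    mat <- .applyMissingness(mat, spec)

    flags <- list(con = rep(FALSE, length(ids)), rev = rep(FALSE, length(ids)))
    genes <- paste0("g", seq_along(ids))
    mw <- round(stats::runif(length(ids), 10, 150), 3)
    reportPath <- file.path(dir, "proteinGroups.txt")
    .writeDialect(mat, ids, genes, mw, samples, flags, "maxquant", reportPath)

    anchorPath <- file.path(dir, "anchors.tsv")
    utils::write.table(data.frame(accession = names(anchors), fmol = anchors),
                       anchorPath, sep = "\t", quote = FALSE, row.names = FALSE)
    standardsPath <- file.path(dir, "enrichment_standards.tsv")
    utils::write.table(
      data.frame(accession = names(stdStocks), stock_fmol_per_ul = stdStocks),
      standardsPath, sep = "\t", quote = FALSE, row.names = FALSE)

    params <- data.frame(check.names = FALSE, stringsAsFactors = FALSE,
      Condition = c("Base", "Enriched"),
      SampleVolume = sampleVolumeUl, ProteinConcentration = proteinConcUgPerUl,
      AmountMS = amountMSUg, CellsPerML = cellsPerMl,
      TotalCultureVolume = cultureVolumeUl,
      Enrichment = c("FALSE", "TRUE"),
      EnrichmentMode = c("", "Enrichment"),
      StdDilution = c("", as.character(stdDilution)),
      StdVolume = c("", as.character(stdVolumeUl)))
    paramsPath <- file.path(dir, "experimental_params.tsv")
    utils::write.table(params, paramsPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)

    truth <- data.frame(proteinId = prot, trueFmolMS = baseFmol,
                        stringsAsFactors = FALSE)
    list(reportPath = reportPath, anchorPath = anchorPath,
         standardsPath = standardsPath, paramsPath = paramsPath,
         truth = truth, factor = f, standards = stdStocks, samples = samples)
  })
}
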
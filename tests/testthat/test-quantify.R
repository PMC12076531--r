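# independent closed-form least-squares oracle for log-log fits
olsOracle <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - a - b * x
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  s2 <- sum(res^2) / (n - 2)
  list(slope = b, intercept = a, r2 = r2,
       seSlope = sqrt(s2 / sum((x - mean(x))^2)),
       seIntercept = sqrt(s2 * (1 / n + mean(x)^2 / sum((x - mean(x))^2))))
}

anchorFixture <- function(intens, amounts = c(A = 1, B = 10, C = 100)) {
  tf <- maxquantFixture(names(amounts),
                        list(S1 = intens))
  list(report = readReport(tf),
       anchors = new("AnchorSet", amounts = amounts, sourcePath = "inline"))
}

test_that("anchor tables parse from TSV/CSV and reject bad rows", {
  tf <- writeTsvLines(c("P00915\t500", "P02768\t5"))
  a <- readAnchors(tf)
  expect_identical(anchorAmounts(a), c(P00915 = 500, P02768 = 5))

  withHeader <- writeTsvLines(c("accession\tfmol", "P00915\t500", "P02768\t5"))
  expect_identical(anchorAmounts(readAnchors(withHeader)), anchorAmounts(a))

  csv <- tempfile(fileext = ".csv")
  writeLines(c("P00915,500", "P02768,5"), csv)
  expect_identical(anchorAmounts(readAnchors(csv)), anchorAmounts(a))

  expect_error(readAnchors(writeTsvLines(c("P1\t10", "P1\t20"))), "duplicate")
  expect_error(readAnchors(writeTsvLines(c("P1\t10", "P2\t-1"))),
               "non-positive.*row 2")
})

test_that("a perfect log-log line is recovered exactly", {
  fx <- anchorFixture(c(1e4, 1e5, 1e6))
  m <- fitAnchors(fx$report, fx$anchors, "iBAQ", "S1")
  expect_equal(m@slope, 1, tolerance = 1e-9)
  expect_equal(m@intercept, 4, tolerance = 1e-9)
  expect_equal(m@rSquared, 1, tolerance = 1e-9)
  expect_identical(m@nAnchorsUsed, 3L)
})

test_that("OLS coefficients match the closed-form oracle on noisy points", {
  fx <- anchorFixture(c(2e4, 1e5, 9e5))
  m <- fitAnchors(fx$report, fx$anchors, "iBAQ", "S1")
  o <- olsOracle(log10(c(1, 10, 100)), log10(c(2e4, 1e5, 9e5)))
  expect_equal(m@slope, o$slope, tolerance = 1e-12)
  expect_equal(m@intercept, o$intercept, tolerance = 1e-12)
  expect_equal(m@rSquared, o$r2, tolerance = 1e-12)
  # R^2 equals the squared Pearson correlation of the fitted points
  expect_equal(m@rSquared,
               cor(log10(c(1, 10, 100)), log10(c(2e4, 1e5, 9e5)))^2,
               tolerance = 1e-12)
})

test_that("fitting fails cleanly below 3 anchors or at zero amount variance", {
  fx <- anchorFixture(c(1e4, 1e5, NA))
  fx$report@intensities$iBAQ[3, 1] <- NA
  expect_error(fitAnchors(fx$report, fx$anchors, "iBAQ", "S1"),
               "insufficient anchors")
  fx2 <- anchorFixture(c(1e4, 1e5, 1e6), amounts = c(A = 5, B = 5, C = 5))
  expect_error(fitAnchors(fx2$report, fx2$anchors, "iBAQ", "S1"),
               "zero variance")
})

test_that("imputed anchor intensities are excluded unless asked for", {
  fx <- anchorFixture(c(1e4, 1e5, 1e6, 1e7),
                      amounts = c(A = 1, B = 10, C = 100, D = 1000))
  mask <- array(FALSE, dim = dim(fx$report@intensities$iBAQ),
                dimnames = dimnames(fx$report@intensities$iBAQ))
  mask[4, 1] <- TRUE
  fx$report@imputed$iBAQ <- mask
  m <- fitAnchors(fx$report, fx$anchors, "iBAQ", "S1")
  expect_identical(m@nAnchorsUsed, 3L)
  expect_identical(m@anchorsExcluded, "D")
  m2 <- fitAnchors(fx$report, fx$anchors, "iBAQ", "S1", includeImputed = TRUE)
  expect_identical(m2@nAnchorsUsed, 4L)
})

test_that("parameters are recovered from noisy staggered-decade anchors", {
  spec <- syntheticSpec(nProteins = 10L, nConditions = 1L, nReplicates = 1L,
                        intercept = 4.2, slope = 0.95, noiseSigma = 0.12,
                        nContaminants = 0L, nReverse = 0L, seed = 13L)
  g <- makeReport(spec, "maxquant")
  rep <- readReport(g$reportPath)
  a <- readAnchors(g$anchorPath)
  m <- fitAnchors(rep, a, "iBAQ", "Cond1_1")
  expect_identical(m@nAnchorsUsed, 48L)
  rows <- match(names(anchorAmounts(a)), firstAccessions(rep))
  o <- olsOracle(log10(anchorAmounts(a)),
                 log10(intensityMatrix(rep, "iBAQ")[rows, 1]))
  expect_lt(abs(m@slope - 0.95), 3 * o$seSlope)
  expect_lt(abs(m@intercept - 4.2), 3 * o$seIntercept)
})

test_that("inverting the calibration reproduces amounts", {
  fx <- anchorFixture(c(1e4, 1e5, 1e6))
  m <- fitAnchors(fx$report, fx$anchors, "iBAQ", "S1")
  res <- estimateAmounts(fx$report, m)
  q <- quantTable(res)
  # model (slope 1, intercept 4): intensity 1e5 -> 10 fmol
  expect_equal(q$fmolMS[q$proteinId == "B"], 10, tolerance = 1e-9)
  # on a perfect line the anchors round-trip exactly
  expect_equal(q$fmolMS[match(c("A", "B", "C"), q$proteinId)],
               c(1, 10, 100), tolerance = 1e-9)
})

test_that("per-protein estimates track planted amounts within the noise bound", {
  sigma <- 0.12
  spec <- syntheticSpec(nProteins = 300L, nConditions = 1L, nReplicates = 2L,
                        noiseSigma = sigma, seed = 17L)
  g <- makeReport(spec, "maxquant")
  rep <- removeFlagged(readReport(g$reportPath))
  res <- quantifyReport(rep, readAnchors(g$anchorPath), "iBAQ")
  q <- quantTable(res)
  q1 <- q[q$sample == "Cond1_1", ]
  truth <- g$truth$trueFmolMS[match(q1$proteinId, g$truth$proteinId)]
  relErr <- abs(q1$fmolMS / truth - 1)
  expect_lt(median(relErr), 2 * sigma)
})

test_that("rescaling a sample shifts the intercept only", {
  fx <- anchorFixture(c(2e4, 1e5, 9e5))
  m1 <- fitAnchors(fx$report, fx$anchors, "iBAQ", "S1")
  r1 <- quantTable(estimateAmounts(fx$report, m1))$fmolMS
  k <- 7.3
  fx$report@intensities$iBAQ <- fx$report@intensities$iBAQ * k
  m2 <- fitAnchors(fx$report, fx$anchors, "iBAQ", "S1")
  r2 <- quantTable(estimateAmounts(fx$report, m2))$fmolMS
  expect_equal(m2@slope, m1@slope, tolerance = 1e-9)
  expect_equal(m2@rSquared, m1@rSquared, tolerance = 1e-9)
  expect_equal(m2@intercept - m1@intercept, log10(k), tolerance = 1e-9)
  # relative abundances within the sample are unchanged
  expect_equal(r2 / r2[1], r1 / r1[1], tolerance = 1e-9)
})

test_that("consult ranks candidates by mean R^2 with deterministic ties", {
  # one candidate: recommended with its own R^2
  fx <- anchorFixture(c(2e4, 1e5, 9e5))
  tab <- consult(fx$report, fx$anchors, candidateMethods = "iBAQ",
                 candidateNormalizations = "none")
  expect_identical(nrow(tab), 1L)
  m <- fitAnchors(fx$report, fx$anchors, "iBAQ", "S1")
  expect_equal(tab$meanRSquared, m@rSquared, tolerance = 1e-12)

  # a per-sample distortion that median normalization removes ranks
  # (median) above (none)
  set.seed(31)
  amounts <- setNames(10^runif(24, -1, 3), sprintf("A%02d", 1:24))
  base <- 1e5 * amounts
  noisy1 <- base * 10^rnorm(24, 0, 0.05)
  noisy2 <- base * 10^rnorm(24, 0, 0.05) * 40   # heavy per-sample distortion
  tf <- maxquantFixture(names(amounts), list(S1 = noisy1, S2 = noisy2))
  rep <- readReport(tf)
  anchors <- new("AnchorSet", amounts = amounts, sourcePath = "inline")
  tab2 <- consult(rep, anchors, candidateMethods = "iBAQ",
                  candidateNormalizations = c("none", "median"))
  expect_identical(tab2$normalization[1], "median")

  # noiseless data: every candidate at R^2 = 1, ties broken by name
  tfp <- maxquantFixture(names(amounts), list(S1 = base, S2 = base * 2))
  repp <- readReport(tfp)
  tab3 <- consult(repp, anchors, candidateMethods = "iBAQ",
                  candidateNormalizations = c("total_sum", "none", "median"))
  expect_equal(tab3$meanRSquared, rep(1, 3), tolerance = 1e-9)
  expect_identical(tab3$normalization, c("median", "none", "total_sum"))
  # determinism
  expect_identical(tab3, consult(repp, anchors, candidateMethods = "iBAQ",
                                 candidateNormalizations = c("total_sum", "none", "median")))
})

test_that("anchors matched by several protein groups are dropped with a warning", {
  tf <- writeTsvLines(c(
    "Protein IDs\tMajority protein IDs\tiBAQ S1",
    "A;X\tA\t1e4", "A;Y\tA\t2e4", "B\tB\t1e5", "C\tC\t1e6", "D\tD\t1e7"))
  rep <- readReport(tf)
  anchors <- new("AnchorSet", amounts = c(A = 1, B = 10, C = 100, D = 1000),
                 sourcePath = "inline")
  expect_warning(m <- fitAnchors(rep, anchors, "iBAQ", "S1"), "multiple")
  expect_identical(m@nAnchorsUsed, 3L)
  expect_true("A" %in% m@anchorsExcluded)
})
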
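exampleParamsPath <- function() {
  system.file("extdata", "experimental_params_example.tsv",
              package = "anchorQuant")
}

test_that("the canonical three-row parameters table parses exactly", {
  p <- paramsTable(readParams(exampleParamsPath()))
  expect_identical(p$condition, c("Cond1_t0", "Cond2_t1", "Cond3_t2"))
  expect_identical(p$sampleVolumeUl, c(2.31, 2.5, 7.38))
  expect_identical(p$proteinConcUgPerUl, c(2.99, 0.2, 6.56))
  expect_identical(p$amountMSUg, c(9.67, 4.1, 2.77))
  expect_identical(p$cellsPerMl, c(4.54, 5.13, 3.66))
  expect_identical(p$totalCultureVolume, c(7.54, 2.62, 3.8))
  expect_identical(p$enrichment, c(FALSE, TRUE, TRUE))
  expect_identical(p$enrichmentMode, c(NA, "Concentration", "Enrichment"))
  expect_identical(p$stdDilution, c(NA, 10, 2))
  expect_identical(p$stdVolumeUl, c(NA, 10, 10))
  expect_identical(p$proteinSRM, list("TNAMLN", "AJFVYC", "BYEKSC"))
  expect_identical(p$fmolSRM, list(4.44, 4.85, 9.71))
})

test_that("parameter validation enforces the schema rules", {
  # enrichment TRUE without mode and without SRM columns
  bad <- paramsFixture(data.frame(
    Condition = "C1", SampleVolume = 1, ProteinConcentration = 1,
    AmountMS = 1, CellsPerML = 1, TotalCultureVolume = 1,
    Enrichment = "TRUE"))
  expect_error(readParams(bad), "Enrichment is TRUE")

  # missing mandatory column is named
  bad2 <- paramsFixture(data.frame(Condition = "C1", SampleVolume = 1))
  expect_error(readParams(bad2), "ProteinConcentration")

  # optional SRM columns absent: fields come back empty
  ok <- paramsFixture(data.frame(
    Condition = "C1", SampleVolume = 1, ProteinConcentration = 2,
    AmountMS = 0.5, CellsPerML = 1e8, TotalCultureVolume = 1000))
  p <- paramsTable(readParams(ok))
  expect_identical(p$proteinSRM, list(character(0)))
  expect_false(p$enrichment)

  # headers match case-insensitively
  ci <- paramsFixture(setNames(
    data.frame("C1", 1, 2, 0.5, 1e8, 1000),
    c("condition", "samplevolume", "PROTEINCONCENTRATION", "amountms",
      "cellsperml", "totalculturevolume")))
  expect_identical(paramsTable(readParams(ci))$amountMSUg, 0.5)

  # comma-separated SRM lists pair up
  srm <- paramsFixture(data.frame(
    Condition = "C1", SampleVolume = 1, ProteinConcentration = 2,
    AmountMS = 0.5, CellsPerML = 1e8, TotalCultureVolume = 1000,
    Enrichment = "TRUE", ProteinSRM = "P1,P2", fmolSRM = "4.0,6.0"))
  p2 <- paramsTable(readParams(srm))
  expect_identical(p2$proteinSRM[[1]], c("P1", "P2"))
  expect_identical(p2$fmolSRM[[1]], c(4.0, 6.0))
})

enrichParams <- function(stdDilution = 10, stdVolume = 10,
                         sampleVolume = 10, proteinConc = 5, amountMS = 5) {
  readParams(paramsFixture(data.frame(
    Condition = "Enr", SampleVolume = sampleVolume,
    ProteinConcentration = proteinConc, AmountMS = amountMS,
    CellsPerML = 1e8, TotalCultureVolume = 1000,
    Enrichment = "TRUE", EnrichmentMode = "Enrichment",
    StdDilution = stdDilution, StdVolume = stdVolume)))
}

test_that("enrichment factors follow the spiked-standard arithmetic", {
  # stock 100 fmol/uL / dilution 10 x 10 uL = 100 fmol added; 50 ug total,
  # 5 ug injected -> expected MS share 10 fmol; measured 20 -> factor 2
  params <- enrichParams()
  std <- new("EnrichmentStandards", stocks = c(S1 = 100), sourcePath = "x")
  res <- quantResultFixture("S1", "Enr_1", 20)
  f <- computeEnrichment(res, params, std, "Enr")
  expect_equal(enrichmentValue(f), 2.0, tolerance = 1e-12)
  expect_identical(f@basis, "spiked_standards")

  # two standards at ratios 2 and 4: median is the midpoint, 3
  std2 <- new("EnrichmentStandards", stocks = c(S1 = 100, S2 = 100),
              sourcePath = "x")
  res2 <- quantResultFixture(c("S1", "S2"), c("Enr_1", "Enr_1"), c(20, 40))
  expect_equal(enrichmentValue(computeEnrichment(res2, params, std2, "Enr")),
               3.0, tolerance = 1e-12)

  # a standard absent from the result is skipped with a warning
  expect_warning(
    f3 <- computeEnrichment(res, params, std2, "Enr"), "not quantified")
  expect_identical(f3@nStandards, 1L)
})

test_that("SRM-supplied enrichment is the median of measured/supplied ratios", {
  params <- readParams(paramsFixture(data.frame(
    Condition = "Enr", SampleVolume = 10, ProteinConcentration = 5,
    AmountMS = 5, CellsPerML = 1e8, TotalCultureVolume = 1000,
    Enrichment = "TRUE", ProteinSRM = "P1,P2", fmolSRM = "10,5")))
  # ratios 30/10 = 3 alone; {2, 8} -> median 5
  res <- quantResultFixture("P1", "Enr_1", 30)
  expect_warning(f <- srmEnrichment(res, params, "Enr"), "not quantified")
  expect_equal(enrichmentValue(f), 3.0, tolerance = 1e-12)
  expect_identical(f@basis, "srm_supplied")

  res2 <- quantResultFixture(c("P1", "P2"), c("Enr_1", "Enr_1"), c(20, 40))
  expect_equal(enrichmentValue(srmEnrichment(res2, params, "Enr")), 5.0,
               tolerance = 1e-12)

  # nothing usable is an error
  res3 <- quantResultFixture("other", "Enr_1", 1)
  expect_error(suppressWarnings(srmEnrichment(res3, params, "Enr")),
               "no usable")
})

test_that("absolute units follow the unit arithmetic exactly", {
  params <- readParams(paramsFixture(data.frame(
    Condition = "C", SampleVolume = 2, ProteinConcentration = 5,
    AmountMS = 5, CellsPerML = 1e8, TotalCultureVolume = 1000)))
  res <- quantResultFixture("P1", "C_1", 10)
  out <- quantTable(toAbsolute(res, params, molWeights = c(P1 = 50)))
  # 10 fmol at MS, 2 uL x 5 ug/uL = 10 ug total of which 5 ug injected
  expect_equal(out$fmolTotal, 20, tolerance = 1e-9)
  # 10 fmol x 50 kDa x 1e-3 / 5 ug = 0.1 ng/ug
  expect_equal(out$ngPerUg, 0.1, tolerance = 1e-9)
  # 20 fmol in 1e8 cells (1e8 cells/mL x 1 mL culture)
  expect_equal(out$moleculesPerCell, 20e-15 * 6.02214076e23 / 1e8,
               tolerance = 1e-9)
  expect_false(out$enrichmentCorrected)

  # linearity: doubling fmolMS doubles all three units
  res2 <- quantResultFixture("P1", "C_1", 20)
  out2 <- quantTable(toAbsolute(res2, params, molWeights = c(P1 = 50)))
  expect_equal(out2$fmolTotal, 2 * out$fmolTotal, tolerance = 1e-12)
  expect_equal(out2$ngPerUg, 2 * out$ngPerUg, tolerance = 1e-12)
  expect_equal(out2$moleculesPerCell, 2 * out$moleculesPerCell,
               tolerance = 1e-12)

  # doubling the cell count halves molecules per cell only
  params2 <- readParams(paramsFixture(data.frame(
    Condition = "C", SampleVolume = 2, ProteinConcentration = 5,
    AmountMS = 5, CellsPerML = 2e8, TotalCultureVolume = 1000)))
  out3 <- quantTable(toAbsolute(res, params2, molWeights = c(P1 = 50)))
  expect_equal(out3$moleculesPerCell, out$moleculesPerCell / 2,
               tolerance = 1e-12)
  expect_equal(out3$fmolTotal, out$fmolTotal, tolerance = 1e-12)

  # culture volume in mL convention scales cells by 1000
  pml <- readParams(paramsFixture(data.frame(
    Condition = "C", SampleVolume = 2, ProteinConcentration = 5,
    AmountMS = 5, CellsPerML = 1e8, TotalCultureVolume = 1)),
    cultureVolumeUnit = "mL")
  outml <- quantTable(toAbsolute(res, pml, molWeights = c(P1 = 50)))
  expect_equal(outml$moleculesPerCell, out$moleculesPerCell,
               tolerance = 1e-12)

  # missing MW leaves ngPerUg unset with a warning
  expect_warning(
    outw <- quantTable(toAbsolute(res, params, molWeights = c(other = 1))),
    "molecular weight")
  expect_true(is.na(outw$ngPerUg))

  # unmatched condition is an error
  resx <- quantResultFixture("P1", "X_1", 10)
  expect_error(toAbsolute(resx, params), "no parameters row")
})

test_that("a factor of 1 leaves corrected and uncorrected outputs identical", {
  params <- enrichParams()
  res <- quantResultFixture(c("P1", "P2"), c("Enr_1", "Enr_1"), c(10, 3))
  f1 <- new("EnrichmentFactor", condition = "Enr", factor = 1,
            nStandards = 3L, basis = "spiked_standards")
  with_f <- quantTable(toAbsolute(res, params, factors = f1))
  without <- quantTable(toAbsolute(res, params))
  expect_equal(with_f$fmolTotal, without$fmolTotal, tolerance = 1e-12)
  expect_equal(with_f$moleculesPerCell, without$moleculesPerCell,
               tolerance = 1e-12)
  expect_true(all(with_f$enrichmentCorrected))
  expect_false(any(without$enrichmentCorrected))

  # a real factor divides fmolTotal and molecules per cell
  f5 <- new("EnrichmentFactor", condition = "Enr", factor = 5,
            nStandards = 3L, basis = "spiked_standards")
  corr <- quantTable(toAbsolute(res, params, factors = f5))
  expect_equal(corr$fmolTotal, without$fmolTotal / 5, tolerance = 1e-12)
  expect_equal(corr$moleculesPerCell, without$moleculesPerCell / 5,
               tolerance = 1e-12)
})

test_that("mass closure holds when the report covers the whole proteome", {
  # noiseless proteome where the injected amount equals the summed protein
  # mass: the ng/ug shares must add up to 1000 ng per ug
  spec <- syntheticSpec(nProteins = 150L, nConditions = 1L, nReplicates = 2L,
                        nContaminants = 0L, nReverse = 0L, seed = 19L)
  g <- makeReport(spec, "maxquant")
  rep <- readReport(g$reportPath)
  res <- quantifyReport(rep, readAnchors(g$anchorPath), "iBAQ")
  mwAll <- molWeights(rep)
  q1 <- quantTable(res)
  q1 <- q1[q1$sample == "Cond1_1", ]
  totalMassUg <- sum(q1$fmolMS * mwAll[q1$proteinId] * 1e-3) * 1e-3  # ng->ug
  params <- readParams(paramsFixture(data.frame(
    Condition = "Cond1", SampleVolume = 1, ProteinConcentration = 1,
    AmountMS = totalMassUg, CellsPerML = 1e8, TotalCultureVolume = 1000)))
  out <- quantTable(toAbsolute(res, params, molWeights = mwAll))
  bySample <- tapply(out$ngPerUg, out$sample, sum)
  expect_equal(unname(bySample["Cond1_1"]), 1000, tolerance = 1e-6)
  expect_true(all(bySample <= 1000 * (1 + 0.5)))
})

test_that("molecular weights derive from FASTA sequences", {
  ff <- tempfile(fileext = ".fasta")
  writeLines(c(">sp|P1|TEST1 something", "GG", ">P2 plain", "AC"), ff)
  mw <- molWeightsFromFasta(ff)
  expect_equal(mw[["P1"]], (2 * 57.0519 + 18.01528) / 1000, tolerance = 1e-9)
  expect_equal(mw[["P2"]], (71.0788 + 103.1388 + 18.01528) / 1000,
               tolerance = 1e-9)
})
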
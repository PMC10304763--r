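test_that("makeSyntheticAtlas plants one-hot markers at full contrast", {
  syn <- makeSyntheticAtlas(nCellTypes = 3, nCpGs = 120, nMarkersPerType = 4,
                            markerContrast = 1, seed = 40)
  b <- betaValues(syn$atlas)
  hyper <- syn$truth[syn$truth$direction == "hyper", ]
  for (i in seq_len(nrow(hyper))) {
    row <- b[hyper$probe_id[i], ]
    expect_equal(unname(row[hyper$cell_type[i]]), 1)
    expect_true(all(row[setdiff(names(row), hyper$cell_type[i])] == 0))
  }

  syn2 <- makeSyntheticAtlas(nCellTypes = 3, nCpGs = 120, nMarkersPerType = 4,
                             markerContrast = 1, seed = 40)
  expect_identical(betaValues(syn$atlas), betaValues(syn2$atlas))

  expect_error(makeSyntheticAtlas(nCellTypes = 5, nCpGs = 30,
                                  nMarkersPerType = 10, seed = 1),
               "infeasible")
})

test_that("simulated cohorts have valid counts and seed determinism", {
  syn <- makeSyntheticAtlas(nCellTypes = 4, nCpGs = 600, nMarkersPerType = 5,
                            seed = 41)
  spec <- cohortSpec(groupSizes = c(control = 3L, STEMI = 3L, NSTEMI = 2L,
                                    UA = 2L),
                     nPlantedDMRs = 3L, nSeverityWindows = 2L, seed = 42)
  coh <- simulateWGBSCohort(spec, syn$atlas)
  expect_identical(length(coh$calls), 10L)
  for (cs in coh$calls) {
    cl <- methCalls(cs)
    expect_true(all(cl$meth >= 0 & cl$meth <= cl$cov))
    expect_true(all(cl$cov >= 1))
  }
  expect_true(all(coh$trueBeta >= 0 & coh$trueBeta <= 1))
  expect_identical(nrow(coh$sheet), 10L)
  expect_true(all(coh$sheet$ccfdna_ng_per_ml >= 0))

  coh2 <- simulateWGBSCohort(spec, syn$atlas)
  expect_identical(coh$trueBeta, coh2$trueBeta)
  expect_identical(methCalls(coh$calls[[1]]), methCalls(coh2$calls[[1]]))
})

test_that("a null cohort produces no DMR calls beyond the nominal rate", {
  syn <- makeSyntheticAtlas(nCellTypes = 4, nCpGs = 1000, nMarkersPerType = 5,
                            seed = 43)
  # identical proportions in all groups and no planted effects
  p <- defaultGroupProportions(syn$atlas)
  p[] <- rep(p["control", ], each = 4)
  spec <- cohortSpec(groupSizes = c(control = 5L, STEMI = 5L),
                     nPlantedDMRs = 1L, delta = 0.1, nSeverityWindows = 0L,
                     severitySlope = 0, seed = 44)
  coh <- simulateWGBSCohort(spec, syn$atlas, trueProportions = p)
  tiles <- tileCounts(coh$calls)
  res <- dmTest(tiles, coh$sheet$sample[coh$sheet$group == "STEMI"],
                coh$sheet$sample[coh$sheet$group == "control"])
  res$q_value <- adjustQvalues(res$p_value)
  expect_lte(nrow(callDMRs(res)), 1L)
  expect_lt(mean(res$p_value <= 0.05), 0.1)
})

test_that("deconvolution of simulated samples recovers the group proportions", {
  syn <- makeSyntheticAtlas(nCellTypes = 5, nCpGs = 1500, nMarkersPerType = 10,
                            markerContrast = 0.9, seed = 45)
  sig <- buildSignatureMatrix(syn$atlas, selectionConfig(kTop = 10, kDiff = 15))
  spec <- cohortSpec(groupSizes = c(control = 3L, STEMI = 3L),
                     nPlantedDMRs = 1L, delta = 1, nSeverityWindows = 0L,
                     coverageLambda = 30, seed = 46)
  coh <- simulateWGBSCohort(spec, syn$atlas,
                            excludeProbes = syn$truth$probe_id)
  coords <- probeCoords(syn$atlas)
  manifest <- data.frame(probe_id = names(coords),
                         chrom = as.character(GenomicRanges::seqnames(coords)),
                         pos = GenomicRanges::start(coords), strand = "+")
  truthP <- coh$truth$proportions
  for (s in coh$sheet$sample[1:3]) {
    bulk <- mapToProbes(collapseStrands(coh$calls[[s]]), manifest)
    p <- attr(deconvolute(bulk, sig, "nnls"), "proportions")
    g <- coh$sheet$group[coh$sheet$sample == s]
    expect_lt(max(abs(p[colnames(truthP)] - truthP[g, ])), 0.08)
  }
})

test_that("the targeted panel reproduces cohort methylation absent distortion", {
  syn <- makeSyntheticAtlas(nCellTypes = 3, nCpGs = 500, nMarkersPerType = 4,
                            seed = 47)
  spec <- cohortSpec(groupSizes = c(control = 2L, STEMI = 2L),
                     nPlantedDMRs = 2L, nSeverityWindows = 0L, seed = 48)
  coh <- simulateWGBSCohort(spec, syn$atlas)
  pan <- simulateTargetedPanel(coh, panelWindows = coh$truth$dmrs$window,
                               batchShift = 0, batchScale = 1,
                               coverageLambda = 200, seed = 49)
  expect_identical(names(pan$calls), colnames(coh$trueBeta))
  expect_identical(unique(pan$sheet$batch), "validation")
  s <- names(pan$calls)[1]
  cl <- methCalls(pan$calls[[s]])
  truth <- coh$trueBeta[, s]
  key <- paste(cl$chrom, cl$pos)
  coords <- probeCoords(syn$atlas)
  akey <- paste(as.character(GenomicRanges::seqnames(coords)),
                GenomicRanges::start(coords))
  betaHat <- cl$meth / cl$cov
  expect_lt(mean(abs(betaHat - truth[match(key, akey)])), 0.05)

  pan2 <- simulateTargetedPanel(coh, panelWindows = coh$truth$dmrs$window,
                                batchShift = 0, batchScale = 1,
                                coverageLambda = 200, seed = 49)
  expect_identical(methCalls(pan2$calls[[s]]), cl)

  expect_error(simulateTargetedPanel(coh, panelWindows = "chrZ:1"),
               "panel is empty")
})
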
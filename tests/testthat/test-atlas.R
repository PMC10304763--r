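test_that("mergeAtlases joins by probe ID and rejects duplicate labels", {
  a <- toyAtlas(matrix(c(.1, .9), 2, 1, dimnames = list(c("p1", "p2"), "A")))
  b <- toyAtlas(matrix(c(.5, .7), 2, 1, dimnames = list(c("p2", "p3"), "B")))
  inner <- mergeAtlases(a, b)
  expect_identical(probeIDs(inner), "p2")
  expect_identical(cellTypes(inner), c("A", "B"))
  expect_equal(unname(betaValues(inner)["p2", ]), c(.9, .5))

  expect_error(mergeAtlases(a, a), "duplicate cell-type labels")

  # outer join: 5 base probes x 2 types, 3 overlapping ext probes x 1 type
  base <- toyAtlas(matrix(seq(0.1, 1, length.out = 10), 5, 2,
                          dimnames = list(paste0("p", 1:5), c("A", "B"))))
  ext <- toyAtlas(matrix(c(.2, .4, .6), 3, 1,
                         dimnames = list(c("p2", "p4", "p5"), "C")))
  outer <- mergeAtlases(base, ext, join = "outer")
  expect_identical(probeIDs(outer), paste0("p", 1:5))
  expect_equal(sum(is.na(betaValues(outer)[, "C"])), 2L)
  expect_true(all(is.na(betaValues(outer)[c("p1", "p3"), "C"])))
  expect_equal(unname(betaValues(outer)[c("p2", "p4", "p5"), "C"]),
               c(.2, .4, .6))
})

test_that("filterAndPool drops missing/low-variance rows and pools replicates", {
  m <- rbind(constant = c(0.5, 0.5, 0.5, 0.5),
             missing = c(0.1, NA, 0.9, 0.2),
             keep = c(0.2, 0.4, 0.9, 0.8))
  colnames(m) <- c("A_rep1", "A_rep2", "B_rep1", "B_rep2")
  pooled <- filterAndPool(MethylationAtlas(m))
  expect_identical(probeIDs(pooled), "keep")
  expect_equal(betaValues(pooled)["keep", "A"], 0.3)  # mean(0.2, 0.4)
  expect_equal(betaValues(pooled)["keep", "B"], 0.85)

  expect_error(
    filterAndPool(MethylationAtlas(m[1:2, , drop = FALSE])),
    "no probes left"
  )
})

test_that("selectTopScaled matches a brute-force scaled ranking and honors the exclusion list", {
  # one-hot: each probe methylated in exactly one of 3 types, k = 1
  oneHot <- diag(3) * 0.9
  dimnames(oneHot) <- list(c("cgA", "cgB", "cgC"), c("A", "B", "C"))
  sel <- suppressWarnings(selectTopScaled(MethylationAtlas(oneHot), k = 1))
  expect_identical(sel$hyper, list(A = "cgA", B = "cgB", C = "cgC"))

  # exclusion rule: types A and B share the same best probe p1; A (processed
  # first) takes it, B falls back to its next-ranked probe p2
  m <- rbind(p1 = c(0.80, 0.80, 0.05),   # scaled shares (.48, .48, .03)
             p2 = c(0.30, 0.30, 0.40),   # (.30, .30, .40)
             p3 = c(0.35, 0.30, 0.35))   # (.35, .30, .35)
  colnames(m) <- c("A", "B", "C")
  sel <- suppressWarnings(selectTopScaled(MethylationAtlas(m), k = 1))
  expect_identical(sel$hyper$A, "p1")
  expect_identical(sel$hyper$B, "p2")
  expect_false("p1" %in% sel$hyper$B)

  # 4 probes x 2 types, k = 2: brute-force oracle scales rows and ranks
  m <- rbind(q1 = c(0.8, 0.2), q2 = c(0.3, 0.6), q3 = c(0.5, 0.5),
             q4 = c(0.9, 0.4))
  colnames(m) <- c("A", "B")
  scaled <- m / rowSums(m)
  oracleA <- rownames(m)[order(-scaled[, "A"], rownames(m))][1:2]
  sel <- suppressWarnings(selectTopScaled(MethylationAtlas(m), k = 2))
  expect_identical(sel$hyper$A, oracleA)
  oracleB <- setdiff(rownames(m)[order(-scaled[, "B"], rownames(m))],
                     oracleA)[1:2]
  expect_identical(sel$hyper$B, oracleB)
})

test_that("selectTopScaled is invariant to positive row scaling and yields disjoint sets", {
  set.seed(11)
  m <- matrix(runif(200, 0.05, 0.95), 50, 4,
              dimnames = list(sprintf("cg%03d", 1:50), LETTERS[1:4]))
  sel1 <- selectTopScaled(MethylationAtlas(m), k = 5)
  # row scaling happens before ranking, so multiplying rows by positive
  # constants must not change the hyper selection; build the scaled matrix
  # directly through the same scaled-beta route (values still in [0,1])
  rowConst <- runif(50, 0.2, 1)
  m2 <- m * rowConst
  sel2 <- selectTopScaled(MethylationAtlas(m2), k = 5)
  expect_identical(sel1$hyper, sel2$hyper)

  all_sets <- c(sel1$hyper, sel1$hypo)
  flat <- unlist(all_sets)
  expect_equal(anyDuplicated(flat), 0L)
})

test_that("selectMostDifferential ranks by one-vs-rest evidence", {
  # extreme probe ranks first for its type
  m <- rbind(ex = c(1, 0, 0), mid = c(0.6, 0.4, 0.5), flat = c(0.5, 0.5, 0.5))
  colnames(m) <- c("A", "B", "C")
  sel <- selectMostDifferential(MethylationAtlas(m), k = 1)
  expect_identical(sel$A, "ex")

  # hand-computed score comparison: (0.9,.1,.1) beats (0.6,.4,.5) for type 1
  m2 <- rbind(s1 = c(0.9, 0.1, 0.1), s2 = c(0.6, 0.4, 0.5))
  colnames(m2) <- c("A", "B", "C")
  sc <- function(r) abs(r[1] - mean(r[2:3])) / (sd(r[2:3]) + 1e-6)
  expect_gt(sc(m2["s1", ]), sc(m2["s2", ]))
  sel2 <- selectMostDifferential(MethylationAtlas(m2), k = 2)
  expect_identical(sel2$A, c("s1", "s2"))

  # degenerate: constant rows give no signal but a deterministic result
  m3 <- matrix(0.5, 4, 2, dimnames = list(paste0("c", 1:4), c("A", "B")))
  w <- capture_warnings(sel3 <- selectMostDifferential(MethylationAtlas(m3),
                                                       k = 2))
  expect_match(w, "no differential signal", all = TRUE)
  expect_identical(sel3$A, c("c1", "c2"))

  # F path with replicates: planted difference is detected
  set.seed(3)
  mr <- matrix(runif(40, 0.4, 0.6), 10, 4)
  dimnames(mr) <- list(sprintf("r%02d", 1:10),
                       c("A_rep1", "A_rep2", "B_rep1", "B_rep2"))
  mr["r05", c("A_rep1", "A_rep2")] <- c(0.95, 0.94)
  tm <- setNames(sub("_rep[0-9]+$", "", colnames(mr)), colnames(mr))
  self <- selectMostDifferential(MethylationAtlas(mr), k = 1, tissueMap = tm)
  expect_identical(self$A, "r05")
})

test_that("addNeighbors respects the distance window and chromosome", {
  coords <- data.frame(
    probe_id = c("sel", "near", "far", "otherchrom"),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(1000L, 1049L, 1051L, 1000L), strand = "+")
  m <- matrix(0.5, 4, 2, dimnames = list(coords$probe_id, c("A", "B")))
  atlas <- MethylationAtlas(m, coords)
  out <- addNeighbors("sel", atlas, window = 50)
  expect_true("near" %in% out)       # 49 bp away
  expect_false("far" %in% out)       # 51 bp away
  expect_false("otherchrom" %in% out)

  expect_warning(out2 <- addNeighbors("sel", MethylationAtlas(m), 50),
                 "no coordinates")
  expect_identical(out2, "sel")
})

test_that("addPairwiseSpecific adds max-difference probes per pair", {
  m <- rbind(big = c(0.9, 0.1, 0.5), small = c(0.6, 0.4, 0.5),
             other = c(0.5, 0.5, 0.9))
  colnames(m) <- c("A", "B", "C")
  out <- addPairwiseSpecific(MethylationAtlas(m), selected = character(0))
  expect_true("big" %in% attr(out, "added"))   # |0.9 - 0.1| = 0.8 beats 0.2
  # 3 types -> 3 pairs -> at most 3 additions at kPair = 1
  expect_lte(length(attr(out, "added")), 3L)

  # a probe already selected is skipped
  out2 <- addPairwiseSpecific(MethylationAtlas(m), selected = "big")
  expect_false("big" %in% attr(out2, "added"))
})

test_that("buildSignature deduplicates, records provenance by precedence, and errors when empty", {
  m <- diag(3) * 0.9 + 0.05
  dimnames(m) <- list(c("p1", "p2", "p3"), c("A", "B", "C"))
  atlas <- MethylationAtlas(m)
  sig <- suppressWarnings(  # type C contributes no own probe here
    buildSignature(atlas, list(hyper = list(A = "p1"),
                               hypo = list(B = c("p1", "p2")),
                               neighbor = "p3")))
  expect_identical(probeIDs(sig), c("p1", "p2", "p3"))
  pr <- provenance(sig)
  expect_identical(unname(pr["p1"]), "hyper_topk")  # hyper wins over hypo
  expect_identical(unname(pr["p2"]), "hypo_topk")
  expect_identical(unname(pr["p3"]), "neighbor")

  expect_error(buildSignature(atlas, list()), "empty selection")

  # one-hot toy atlas -> identity-like 3-row signature
  sig2 <- suppressWarnings(
    buildSignature(atlas, selectTopScaled(atlas, k = 1)["hyper"]))
  expect_equal(dim(sig2), c(3L, 3L))
  expect_true(all(diag(betaValues(sig2)) > 0.9))
})

test_that("signature construction recovers planted cell-type markers", {
  syn <- makeSyntheticAtlas(nCellTypes = 6, nCpGs = 1200,
                            nMarkersPerType = 8, markerContrast = 0.9,
                            seed = 21)
  sig <- buildSignatureMatrix(syn$atlas,
                              selectionConfig(kTop = 8, kDiff = 16))
  recovered <- mean(syn$truth$probe_id %in% probeIDs(sig))
  expect_gte(recovered, 0.95)
})

test_that("signature files are byte-identical across repeated builds", {
  syn <- makeSyntheticAtlas(nCellTypes = 4, nCpGs = 400,
                            nMarkersPerType = 5, seed = 8)
  build <- function() buildSignatureMatrix(
    syn$atlas, selectionConfig(kTop = 5, kDiff = 10))
  f1 <- tempfile(); f2 <- tempfile()
  writeSignature(build(), f1)
  writeSignature(build(), f2)
  expect_identical(readLines(f1), readLines(f2))
  # and the round trip preserves the matrix
  rt <- readSignature(f1)
  expect_equal(betaValues(rt), betaValues(build()), tolerance = 1e-12)
})
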
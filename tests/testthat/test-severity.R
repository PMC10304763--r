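test_that("encodeSeverity follows the clinical ordering and control options", {
  g <- c("UA", "NSTEMI", "STEMI", "control")
  expect_equal(encodeSeverity(g, includeControls = TRUE), c(1, 2, 3, 0))
  enc <- encodeSeverity(g, includeControls = FALSE)
  expect_equal(enc[1:3], c(1, 2, 3))
  expect_true(is.na(enc[4]))
  expect_error(encodeSeverity(c("STEMI", "misc")), "unknown group")
})

test_that("fitDMRModel recovers an exact construction and the F = t^2 identity", {
  set.seed(20)
  meth <- runif(30, 20, 80)
  ccf <- rlnorm(30, 2, 0.4)
  # noise-free construction: y depends only on methylation
  y <- 0.05 * meth
  fit <- suppressWarnings(fitDMRModel(y, meth, ccf))  # perfect-fit warning
  expect_equal(fit$beta1, 0.05, tolerance = 1e-10)
  expect_equal(fit$beta2, 0, tolerance = 1e-10)
  expect_lt(fit$p_F, 1e-12)
  expect_equal(fit$F_nested, fit$t_beta1^2, tolerance = 1e-8)

  # noisy fits still satisfy the single-parameter nesting identity
  for (i in 1:5) {
    yy <- 2 + 0.02 * meth + 0.01 * ccf + rnorm(30)
    f <- fitDMRModel(yy, meth, ccf)
    expect_equal(f$F_nested, f$t_beta1^2, tolerance = 1e-8)
    expect_equal(f$p_F, f$p_beta1, tolerance = 1e-10)
  }

  # independence: p is typically non-significant under permuted response
  set.seed(21)
  fNull <- fitDMRModel(sample(y), meth, ccf)
  expect_gt(fNull$p_beta1, 0.05)

  # degenerate methylation is flagged with p = 1
  fConst <- fitDMRModel(y, rep(50, 30), ccf)
  expect_true(fConst$flag)
  expect_equal(fConst$p_beta1, 1)
})

test_that("fitDMRModel agrees with the closed-form normal equations", {
  set.seed(22)
  meth <- runif(12, 0, 100); ccf <- runif(12, 1, 40)
  y <- 1 + 0.03 * meth - 0.02 * ccf + rnorm(12, 0, 0.5)
  X <- cbind(1, meth, ccf)
  betaOracle <- solve(t(X) %*% X, t(X) %*% y)
  fit <- fitDMRModel(y, meth, ccf)
  expect_equal(fit$beta0, betaOracle[1], tolerance = 1e-10)
  expect_equal(fit$beta1, betaOracle[2], tolerance = 1e-10)
  expect_equal(fit$beta2, betaOracle[3], tolerance = 1e-10)
})

test_that("selectAssociatedDMRs filters by p and reports the retained fraction", {
  fits <- data.frame(dmr = c("d1", "d2"), p_beta1 = c(0.01, 0.5))
  out <- selectAssociatedDMRs(fits)
  expect_identical(out$selected$dmr, "d1")
  expect_equal(out$fraction, 50)
  expect_identical(nrow(selectAssociatedDMRs(fits[0, ])$selected), 0L)
  expect_equal(selectAssociatedDMRs(fits, alpha = 1)$fraction, 100)
})

test_that("null severity fits keep the significant fraction near alpha", {
  set.seed(23)
  n <- 30; nDMR <- 1000
  mm <- matrix(runif(nDMR * n, 10, 90), nDMR, n,
               dimnames = list(sprintf("d%04d", 1:nDMR), NULL))
  y <- sample(rep(1:3, each = 10))
  ccf <- rlnorm(n, 2.5, 0.4)
  fits <- fitSeverityModels(mm, y, ccf)
  frac <- mean(fits$p_beta1 <= 0.05)
  expect_gt(frac, 0.03)
  expect_lt(frac, 0.07)
})

test_that("fitMarkerModels links markers to the right DMRs", {
  set.seed(24)
  n <- 24
  mm <- matrix(runif(10 * n, 10, 90), 10, n,
               dimnames = list(paste0("DMR_", 1:10), NULL))
  ccf <- rlnorm(n, 2, 0.3)
  markers <- data.frame(
    linked = 2 * mm["DMR_7", ] + rnorm(n, 0, 1),
    constant = rep(5, n),
    sparse = c(runif(3), rep(NA, n - 3))
  )
  expect_warning(res <- fitMarkerModels(mm, markers, ccf), "sparse")
  lk <- res$fits[res$fits$marker == "linked", ]
  expect_lt(lk$p_beta1[lk$dmr == "DMR_7"], 1e-6)
  expect_gt(min(lk$p_beta1[lk$dmr != "DMR_7"]), 1e-6)
  ct <- res$fits[res$fits$marker == "constant", ]
  expect_true(all(ct$p_beta1 > 0.9))
})

test_that("singleMarkerMultinomial scores separation and degenerate markers", {
  labels <- rep(c("UA", "NSTEMI", "STEMI"), each = 3)
  # marker perfectly separating the classes
  sep <- c(1, 1.1, 0.9, 5, 5.2, 4.9, 9, 9.1, 8.8)
  res <- singleMarkerMultinomial(sep, labels)
  expect_equal(res$rate, 0)
  expect_identical(res$n, 9L)

  # constant marker, balanced classes: majority-vote argmax misses 2/3
  resC <- singleMarkerMultinomial(rep(1, 9), labels)
  expect_equal(resC$rate, 100 * 2 / 3, tolerance = 1e-6)

  # missing marker values are excluded
  resNA <- singleMarkerMultinomial(c(sep[1:6], NA, NA, NA), labels)
  expect_identical(resNA$n, 6L)
})

test_that("trainACSClassifiers separates one-hot features and is seed-stable", {
  skip_if_not_installed("mixOmics")
  set.seed(25)
  labels <- rep(c("control", "UA", "NSTEMI", "STEMI"), each = 6)
  oneHot <- model.matrix(~ 0 + factor(labels))
  colnames(oneHot) <- paste0("f", 1:4)
  feats <- oneHot + matrix(rnorm(length(oneHot), 0, 0.01), nrow(oneHot))
  res <- trainACSClassifiers(feats, labels, cvFolds = 3, cvRepeats = 2,
                             seed = 9)
  for (m in c("rf", "pls", "pmr"))
    expect_equal(res[[m]]$test_accuracy, 1, label = m)

  res2 <- trainACSClassifiers(feats, labels, cvFolds = 3, cvRepeats = 2,
                              seed = 9)
  expect_identical(res$split, res2$split)
  for (m in c("rf", "pls", "pmr"))
    expect_equal(res[[m]]$test_accuracy, res2[[m]]$test_accuracy, label = m)
})

test_that("label-permuted classifiers perform at chance", {
  set.seed(26)
  labels <- rep(c("control", "UA", "NSTEMI", "STEMI"), times = c(8, 6, 7, 8))
  feats <- matrix(rnorm(29 * 15), 29, 15,
                  dimnames = list(NULL, paste0("f", 1:15)))
  perm <- sample(labels)
  res <- trainACSClassifiers(feats, perm, models = "rf", cvFolds = 3,
                             cvRepeats = 2, seed = 10)
  nTest <- 29 - length(res$split)
  k <- round(res$rf$test_accuracy * nTest)
  # not significantly better than guessing the majority class
  chance <- max(table(perm)) / length(perm)
  expect_gt(binom.test(k, nTest, chance, alternative = "greater")$p.value,
            0.01)
})

test_that("pcaEmbed produces sensible embeddings", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(4, 5, 6))
  pc <- pcaEmbed(m)
  expect_equal(pc$coords["a", ], pc$coords["b", ])

  # one varying column: PC1 explains everything
  m2 <- cbind(v = c(1, 5, 9, 13), rep(2, 4), rep(7, 4))
  pc2 <- pcaEmbed(m2)
  expect_equal(pc2$explained[1], 1)

  expect_error(pcaEmbed(m[1, , drop = FALSE]), ">= 2 samples")

  # group-shifted data gets positive silhouette in the PC1-2 plane
  set.seed(27)
  groups <- rep(c("g1", "g2", "g3", "g4"), each = 6)
  shift <- matrix(rep(c(0, 4, 8, 12), each = 6), 24, 10)
  m3 <- shift + matrix(rnorm(240), 24, 10)
  pc3 <- pcaEmbed(m3)
  expect_gt(meanSilhouette(pc3$coords, groups), 0)
})
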
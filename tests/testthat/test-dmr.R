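test_that("tileCounts sums CpGs into anchored windows and filters sparse tiles", {
  s1 <- toyCalls("s1", rep("chr1", 4), c(100L, 400L, 450L, 501L),
                 c(5L, 5L, 2L, 9L), c(10L, 10L, 4L, 10L))
  s2 <- toyCalls("s2", rep("chr1", 4), c(100L, 400L, 450L, 501L),
                 c(1L, 2L, 3L, 4L), c(10L, 10L, 10L, 10L))
  tiles <- tileCounts(list(s1, s2), minCpGs = 3)
  # window [1, 501) holds positions 100, 400, 450; position 501 starts the
  # next window, which has < 3 CpGs and is dropped
  expect_identical(nrow(tiles$windows), 1L)
  expect_identical(tiles$windows$start, 1L)
  expect_identical(tiles$windows$end, 501L)
  expect_identical(unname(tiles$meth[1, "s1"]), 12L)
  expect_identical(unname(tiles$cov[1, "s1"]), 24L)

  # with minCpGs = 1 the boundary CpG gets its own window [501, 1001)
  tiles2 <- tileCounts(list(s1, s2), minCpGs = 1)
  expect_identical(tiles2$windows$start, c(1L, 501L))
})

test_that("dmTest matches the glm binomial likelihood-ratio oracle", {
  set.seed(101)
  nWin <- 20
  meth <- cov <- matrix(0L, nWin, 8,
                        dimnames = list(NULL, paste0("s", 1:8)))
  for (i in seq_len(nWin)) {
    cov[i, ] <- rpois(8, 30) + 1L
    theta <- runif(1, 0.2, 0.8) + c(rep(0, 4), rep(runif(1, -0.15, 0.15), 4))
    meth[i, ] <- rbinom(8, cov[i, ], pmin(0.95, pmax(0.05, theta)))
  }
  tiles <- toyTiles(meth, cov)
  res <- dmTest(tiles, groupA = paste0("s", 5:8), groupB = paste0("s", 1:4))
  grp <- factor(rep(c("B", "A"), each = 4), levels = c("B", "A"))
  for (i in seq_len(nWin)) {
    fit1 <- glm(cbind(meth[i, ], cov[i, ] - meth[i, ]) ~ grp, family = binomial)
    fit0 <- glm(cbind(meth[i, ], cov[i, ] - meth[i, ]) ~ 1, family = binomial)
    pOracle <- pchisq(fit0$deviance - fit1$deviance, 1, lower.tail = FALSE)
    expect_equal(res$p_value[i], pOracle, tolerance = 1e-8)
    # and within an order of magnitude of Fisher's exact on pooled counts
    tab <- rbind(A = c(sum(meth[i, 5:8]), sum(cov[i, 5:8] - meth[i, 5:8])),
                 B = c(sum(meth[i, 1:4]), sum(cov[i, 1:4] - meth[i, 1:4])))
    pF <- fisher.test(tab)$p.value
    expect_lt(abs(log10(res$p_value[i]) - log10(pF)), 1)
  }
})

test_that("dmTest handles exact, null and degenerate windows", {
  meth <- rbind(c(100L, 100L, 100L, 0L, 0L, 0L),   # extreme separation
                c(5L, 5L, 5L, 5L, 5L, 5L),         # identical proportions
                c(0L, 0L, 0L, 0L, 0L, 0L))
  cov <- matrix(100L, 3, 6)
  cov[3, 4:6] <- 0L                                 # zero coverage in group B
  colnames(meth) <- colnames(cov) <- paste0("s", 1:6)
  meth[3, ] <- 0L
  # build tiles by hand; cov = 0 entries are allowed at the matrix level
  tiles <- toyTiles(meth, cov)
  res <- dmTest(tiles, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(res$meth_diff[1], 100)
  expect_lt(res$p_value[1], 1e-10)
  expect_equal(res$meth_diff[2], 0)
  expect_gt(res$p_value[2], 0.99)
  expect_true(res$flag[3])
  expect_equal(res$p_value[3], 1)
  expect_equal(res$meth_diff[3], 0)

  # single sample per group, same 5/10 counts: no difference
  tiles1 <- toyTiles(matrix(c(5L, 5L), 1, 2, dimnames = list(NULL, c("a", "b"))),
                     matrix(c(10L, 10L), 1, 2, dimnames = list(NULL, c("a", "b"))))
  res1 <- dmTest(tiles1, "a", "b")
  expect_equal(res1$meth_diff, 0)

  # swapping groups flips the sign of the difference
  res2 <- dmTest(tiles1, "b", "a")
  expect_equal(res2$meth_diff, -res1$meth_diff)
})

test_that("adjustQvalues reproduces hand-computed BH values and stays monotone", {
  expect_equal(adjustQvalues(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjustQvalues(rep(1, 5)), rep(1, 5))
  expect_equal(adjustQvalues(0.2), 0.2)
  set.seed(15)
  p <- runif(100)
  q <- adjustQvalues(p)
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  q2 <- adjustQvalues(p, method = "pi0")
  expect_true(all(q2 <= q + 1e-12))
  expect_error(adjustQvalues(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("callDMRs applies both cutoffs and assigns direction", {
  tests <- data.frame(chrom = "chr1", start = c(1L, 501L, 1001L),
                      end = c(501L, 1001L, 1501L),
                      meth_diff = c(30, 20, 90),
                      p_value = c(1e-4, 1e-4, 0.02),
                      q_value = c(0.005, 0.005, 0.02))
  out <- callDMRs(tests)
  expect_identical(nrow(out), 1L)           # (q .005, diff 30) only
  expect_identical(out$direction, "hyper")

  # order invariance
  out2 <- callDMRs(tests[c(3, 1, 2), ])
  expect_identical(out, out2)

  # hypo direction by sign
  tests$meth_diff <- -tests$meth_diff
  expect_identical(callDMRs(tests)$direction, "hypo")
})

test_that("compareDMRSets reports specific and shared windows", {
  w <- function(starts) data.frame(chrom = "chr1", start = starts,
                                   end = starts + 500L)
  cmp <- compareDMRSets(list(S = w(c(1L, 501L)), N = w(501L)))
  expect_identical(unname(cmp$specific["S"]), 1L)
  expect_identical(unname(cmp$specific["N"]), 0L)
  expect_identical(unname(as.integer(cmp$shared["S+N"])), 1L)

  cmp2 <- compareDMRSets(list(a = w(1L), b = w(1001L)))
  expect_identical(length(cmp2$shared), 0L)

  cmp3 <- compareDMRSets(list(a = w(1L), b = w(1L), c = w(1L)))
  expect_identical(unname(as.integer(cmp3$shared["a+b+c"])), 1L)
})

test_that("null windows keep the type-I error near nominal (small check)", {
  set.seed(77)
  nWin <- 500
  cov <- matrix(rpois(nWin * 12, 10) + 1L, nWin, 12,
                dimnames = list(NULL, paste0("s", 1:12)))
  meth <- matrix(rbinom(length(cov), cov, 0.5), nWin, 12,
                 dimnames = dimnames(cov))
  res <- dmTest(toyTiles(meth, cov), paste0("s", 1:6), paste0("s", 7:12))
  fpr <- mean(res$p_value <= 0.05)
  expect_gt(fpr, 0.02)
  expect_lt(fpr, 0.09)
})
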
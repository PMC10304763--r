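#' Tile methylation calls into fixed-width genomic windows
#'
#' Partitions each chromosome into `window`-bp tiles anchored at position 1
#' (with `step == window` the tiling is a partition), sums per-sample
#' methylated and total read counts over the CpGs falling in each tile, and
#' drops tiles that do not reach `minCpGs` covered CpGs in every sample.
#'
#' @param calls list of strand-collapsed [MethylationCallSet-class] objects.
#' @param window tile width in bp (default 500).
#' @param step step size in bp; must currently equal `window` (partition
#'   tiling, the convention used throughout this package).
#' @param minCpGs minimum CpGs per tile per sample (default 3).
#' @param minCoverage minimum read coverage per CpG record (default 1).
#' @return list with `windows` (data.frame `chrom`, `start`, `end`;
#'   half-open, width = `window`), and window x sample matrices `meth`,
#'   `cov`, `ncpg`. Sample order follows `calls`.
#' @export
tileCounts <- function(calls, window = 500L, step = 500L, minCpGs = 3L,
                       minCoverage = 1L) {
  if (step != window)
    stop("only partition tiling (step == window) is supported")
  ids <- vapply(calls, sampleID, character(1))
  if (anyDuplicated(ids)) stop("duplicate sample IDs in calls")
  per <- lapply(calls, function(cs) {
    cl <- methCalls(cs)
    if (any(cl$strand == "-"))
      stop("calls must be strand-collapsed before tiling")
    cl <- cl[cl$cov >= minCoverage, , drop = FALSE]
    start <- (cl$pos - 1L) %/% window * window + 1L
    key <- paste0(cl$chrom, ":", start)
    list(key = key,
         meth = tapply(cl$meth, key, sum),
         cov = tapply(cl$cov, key, sum),
         n = tapply(cl$meth, key, length))
  })
  allKeys <- sort(unique(unlist(lapply(per, function(x) unique(x$key)))))
  nS <- length(calls)
  meth <- cov <- ncpg <- matrix(0L, length(allKeys), nS,
                                dimnames = list(allKeys, ids))
  for (j in seq_len(nS)) {
    k <- names(per[[j]]$meth)
    meth[k, j] <- as.integer(per[[j]]$meth)
    cov[k, j] <- as.integer(per[[j]]$cov)
    ncpg[k, j] <- as.integer(per[[j]]$n)
  }
  keep <- rowSums(ncpg >= minCpGs) == nS
  meth <- meth[keep, , drop = FALSE]
  cov <- cov[keep, , drop = FALSE]
  ncpg <- ncpg[keep, , drop = FALSE]
  parts <- strsplit(rownames(meth), ":", fixed = TRUE)
  windows <- data.frame(
    chrom = vapply(parts, `[`, character(1), 1L),
    start = as.integer(vapply(parts, `[`, character(1), 2L)),
    stringsAsFactors = FALSE
  )
  windows$end <- windows$start + as.integer(window)
  ord <- order(windows$chrom, windows$start)
  list(windows = windows[ord, , drop = FALSE],
       meth = meth[ord, , drop = FALSE],
       cov = cov[ord, , drop = FALSE],
       ncpg = ncpg[ord, , drop = FALSE])
}

# x * log(p) with the 0 * log(0) = 0 convention.
.xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))

#' Test windows for differential methylation between two groups
#'
#' Per window, fits a binomial logistic regression of per-sample (methylated,
#' unmethylated) read counts on the group indicator and compares it to the
#' intercept-only model with a 1-df likelihood-ratio chi-square. Because the
#' fitted probability under each model is the pooled (coverage-weighted)
#' group proportion, the statistic is computed in closed form from group
#' count totals; it is identical to `glm(cbind(meth, cov - meth) ~ group,
#' family = binomial)` followed by an LRT. The methylation difference is the
#' pooled percentage-point difference `100 * (pA - pB)`.
#'
#' Windows with zero coverage in either group get `p = 1`, `diff = 0` and
#' `flag = TRUE`.
#'
#' @param tiles value of [tileCounts()].
#' @param groupA,groupB character vectors of sample IDs (condition and
#'   control, respectively; `meth_diff` is A minus B).
#' @return data.frame with one row per window: `chrom`, `start`, `end`,
#'   `meth_diff` (percentage points), `p_value`, `flag`.
#' @export
dmTest <- function(tiles, groupA, groupB) {
  ids <- colnames(tiles$meth)
  if (!all(c(groupA, groupB) %in% ids))
    stop("group sample IDs not found in the tiled counts")
  if (!length(groupA) || !length(groupB))
    stop("need >= 1 sample per group")
  Ma <- rowSums(tiles$meth[, groupA, drop = FALSE])
  Ca <- rowSums(tiles$cov[, groupA, drop = FALSE])
  Mb <- rowSums(tiles$meth[, groupB, drop = FALSE])
  Cb <- rowSums(tiles$cov[, groupB, drop = FALSE])
  flag <- Ca == 0 | Cb == 0
  pa <- ifelse(Ca > 0, Ma / Ca, 0)
  pb <- ifelse(Cb > 0, Mb / Cb, 0)
  p0 <- ifelse(Ca + Cb > 0, (Ma + Mb) / (Ca + Cb), 0)
  ll1 <- .xlogy(Ma, pa) + .xlogy(Ca - Ma, 1 - pa) +
    .xlogy(Mb, pb) + .xlogy(Cb - Mb, 1 - pb)
  ll0 <- .xlogy(Ma + Mb, p0) + .xlogy(Ca + Cb - Ma - Mb, 1 - p0)
  lrt <- pmax(0, 2 * (ll1 - ll0))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  diff <- 100 * (pa - pb)
  p[flag] <- 1; diff[flag] <- 0
  data.frame(tiles$windows, meth_diff = diff, p_value = p, flag = flag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Adjust p-values for multiple testing
#'
#' Default is Benjamini–Hochberg. `"pi0"` additionally rescales the BH values
#' by a Storey-type null-proportion estimate `pi0 = min(1, mean(p > 0.5) /
#' 0.5)`, a transparent stand-in for spline-based q-value estimators. Both
#' are monotone in p.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @param method `"bh"` (default) or `"pi0"`.
#' @return numeric vector of q-values.
#' @export
adjustQvalues <- function(p, method = c("bh", "pi0")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  if (method == "pi0") {
    pi0 <- min(1, mean(p > 0.5, na.rm = TRUE) / 0.5)
    q <- pmin(1, pi0 * q)
  }
  q
}

#' Call differentially methylated regions
#'
#' Keeps windows with `q <= qCutoff` and `|meth_diff| >= diffCutoff`
#' percentage points, assigning direction by the sign of the difference
#' (condition minus control).
#'
#' @param tests data.frame from [dmTest()]; a `q_value` column is computed
#'   via [adjustQvalues()] when absent.
#' @param qCutoff q-value cutoff (default 0.01).
#' @param diffCutoff minimum absolute methylation difference in percentage
#'   points (default 25).
#' @param method multiple-testing method passed to [adjustQvalues()].
#' @return data.frame of DMR records (`chrom`, `start`, `end`, `meth_diff`,
#'   `p_value`, `q_value`, `direction`), sorted by position.
#' @export
callDMRs <- function(tests, qCutoff = 0.01, diffCutoff = 25,
                     method = c("bh", "pi0")) {
  if (!"q_value" %in% names(tests))
    tests$q_value <- adjustQvalues(tests$p_value, match.arg(method))
  keep <- tests$q_value <= qCutoff & abs(tests$meth_diff) >= diffCutoff
  out <- tests[keep, , drop = FALSE]
  out$direction <- ifelse(out$meth_diff > 0, "hyper", "hypo")
  out$flag <- NULL
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare DMR sets across comparisons
#'
#' Matches windows by identical coordinates and summarizes which windows are
#' specific to one comparison and which are shared.
#'
#' @param sets named list (>= 2 elements) of DMR data.frames (columns
#'   `chrom`, `start`, `end`).
#' @return list with `membership` (window x comparison logical data.frame),
#'   `specific` (count of windows unique to each comparison) and `shared`
#'   (counts per non-trivial membership combination).
#' @export
compareDMRSets <- function(sets) {
  if (length(sets) < 2) stop("need >= 2 DMR sets to compare")
  keys <- lapply(sets, function(d) paste0(d$chrom, ":", d$start, "-", d$end))
  allk <- sort(unique(unlist(keys)))
  member <- vapply(keys, function(k) allk %in% k, logical(length(allk)))
  member <- matrix(member, nrow = length(allk),
                   dimnames = list(allk, names(sets)))
  member <- as.data.frame(member)
  nmem <- rowSums(member)
  specific <- vapply(names(sets), function(s) sum(member[[s]] & nmem == 1), 1L)
  combo <- apply(member, 1, function(r) paste(names(sets)[r], collapse = "+"))
  list(membership = member, specific = specific,
       shared = table(combo[nmem > 1]))
}

#' Write DMRs as BED and TSV
#'
#' BED uses 0-based half-open coordinates, name `chrom:start-end`, score
#' `-log10(q)` and strand `"."`.
#'
#' @param dmrs data.frame from [callDMRs()].
#' @param bedPath,tsvPath output paths (either may be `NULL` to skip).
#' @return invisibly, the paths written.
#' @export
writeDMRs <- function(dmrs, bedPath = NULL, tsvPath = NULL) {
  if (!is.null(bedPath)) {
    score <- round(-log10(pmax(dmrs$q_value, 1e-300)), 3)
    bed <- data.frame(dmrs$chrom, dmrs$start - 1L, dmrs$end,
                      sprintf("%s:%d-%d", dmrs$chrom, dmrs$start, dmrs$end),
                      score, ".")
    utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsvPath))
    utils::write.table(dmrs, tsvPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(c(bed = bedPath, tsv = tsvPath))
}

#' Per-window percent methylation matrix
#'
#' Pooled per-sample percent methylation (`100 * meth / cov`) for each tiled
#' window, the feature matrix used by severity models, PCA and classifiers.
#'
#' @param tiles value of [tileCounts()].
#' @param windows optional data.frame (`chrom`, `start`, `end`) restricting
#'   to specific windows (e.g. called DMRs).
#' @return numeric matrix, windows (named `chrom:start-end`) x samples, on
#'   the 0-100 scale; `NA` where a sample has no coverage.
#' @export
methylationMatrix <- function(tiles, windows = NULL) {
  m <- 100 * tiles$meth / ifelse(tiles$cov == 0, NA, tiles$cov)
  rownames(m) <- sprintf("%s:%d-%d", tiles$windows$chrom,
                         tiles$windows$start, tiles$windows$end)
  if (!is.null(windows)) {
    keys <- sprintf("%s:%d-%d", windows$chrom, windows$start, windows$end)
    m <- m[rownames(m) %in% keys, , drop = FALSE]
  }
  m
}
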
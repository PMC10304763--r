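#' Pseudo-count log transform of methylation percentages
#'
#' `t = log((x + 1) / ((100 - x) + 1))` maps a methylation percentage in
#' \[0, 100\] to a finite, symmetric logit-like scale: 50% maps to 0, 0% and
#' 100% map to -log(101) and +log(101).
#'
#' @param x methylation percentages in \[0, 100\] (vector or matrix).
#' @return transformed values, same shape.
#' @export
logitLikeTransform <- function(x) {
  if (any(x < 0 | x > 100, na.rm = TRUE))
    stop("methylation percentages must lie in [0, 100]")
  log((x + 1) / ((100 - x) + 1))
}

#' Back-transform to methylation percentages
#'
#' Analytic inverse of [logitLikeTransform()]:
#' `x = (101 * exp(t) - 1) / (1 + exp(t))`, clipped to \[0, 100\]. The round
#' trip `backTransform(logitLikeTransform(x))` returns `x` to within 1e-9 on
#' \[0, 100\].
#'
#' @param t transformed values.
#' @return methylation percentages in \[0, 100\].
#' @export
backTransform <- function(t) {
  e <- exp(t)
  x <- (101 * e - 1) / (1 + e)
  x[is.infinite(e)] <- 101  # exp overflow: limit of the ratio
  pmax(pmin(x, 100), 0)     # x first: keeps dim/dimnames
}

#' Quantile-normalize samples to a target distribution
#'
#' Per sample (column), values are ranked (average ranks for ties) and
#' replaced by linear interpolation into the sorted target vector at the
#' corresponding quantile positions `(rank - 1) / (n - 1)`. When sample and
#' target lengths match, the sorted values of each normalized sample equal
#' the sorted target exactly; a constant sample maps to the target median.
#' `NA`s are preserved (ranks computed among non-missing values).
#'
#' @param m numeric matrix, features x samples (a vector is treated as one
#'   sample).
#' @param target numeric vector defining the target distribution.
#' @return matrix of the same shape with each column mapped onto the target.
#' @export
quantileNormalizeToTarget <- function(m, target) {
  if (!length(target) || all(is.na(target))) stop("target must be non-empty")
  tq <- sort(target[!is.na(target)])
  probs <- if (length(tq) == 1) 0.5 else seq(0, 1, length.out = length(tq))
  m <- as.matrix(m)
  out <- m
  for (j in seq_len(ncol(m))) {
    x <- m[, j]
    ok <- !is.na(x)
    n <- sum(ok)
    if (n == 0) stop(sprintf("sample column %d is all-missing", j))
    r <- rank(x[ok], ties.method = "average")
    if (n == length(tq) && all(r == round(r))) {
      out[ok, j] <- tq[r]          # equal lengths, no ties: exact mapping
    } else {
      p <- if (n == 1) 0.5 else (r - 1) / (n - 1)
      out[ok, j] <- stats::approx(probs, tq, xout = p, rule = 2)$y
    }
  }
  out
}

#' Empirical-Bayes batch adjustment (ComBat)
#'
#' Removes additive and multiplicative batch effects from a feature x sample
#' matrix using the parametric empirical-Bayes location/scale model
#' (per-batch per-feature location and scale estimates shrunk across features
#' with normal/inverse-gamma priors, then rescaled to the grand model), as
#' implemented in `sva::ComBat()`. No covariates are modeled. Intended to run
#' on the transformed scale (see [logitLikeTransform()]).
#'
#' @param m numeric matrix, features x samples.
#' @param batches batch label per sample (>= 2 batches, each with >= 2
#'   samples).
#' @return adjusted matrix of the same shape.
#' @export
combatAdjust <- function(m, batches) {
  m <- as.matrix(m)
  batches <- as.character(batches)
  if (length(batches) != ncol(m))
    stop("one batch label per sample column required")
  tab <- table(batches)
  if (length(tab) < 2) stop("need >= 2 batches")
  if (any(tab < 2))
    stop("batch(es) with a single sample: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  # ComBat cannot standardize features with zero variance inside a batch;
  # pass them through unadjusted
  okVar <- rep(TRUE, nrow(m))
  for (b in unique(batches)) {
    v <- apply(m[, batches == b, drop = FALSE], 1, stats::var)
    okVar <- okVar & v > 0
  }
  out <- m
  if (any(okVar)) {
    adj <- suppressMessages(
      sva::ComBat(dat = m[okVar, , drop = FALSE], batch = batches,
                  mod = NULL, par.prior = TRUE, prior.plots = FALSE)
    )
    out[okVar, ] <- adj
  }
  if (!all(okVar))
    warning(sprintf("%d features with zero within-batch variance left unadjusted",
                    sum(!okVar)))
  out
}

#' Normalize a targeted validation cohort onto the discovery scale
#'
#' Full cross-platform pipeline: pseudo-count log transform of both percent
#' matrices, quantile normalization of the validation samples to the pooled
#' discovery target distribution, empirical-Bayes batch adjustment of the
#' combined matrix with batch = cohort, and back transformation to the
#' percent scale.
#'
#' @param discovery,validation DMR x sample percent-methylation matrices
#'   sharing row names (DMR IDs); only shared DMRs are used.
#' @return list with `discovery` and `validation` (normalized percent
#'   matrices on the shared DMRs) and `shared` (the DMR IDs used).
#' @export
normalizeValidationCohort <- function(discovery, validation) {
  discovery <- as.matrix(discovery); validation <- as.matrix(validation)
  shared <- intersect(rownames(discovery), rownames(validation))
  if (!length(shared)) stop("no shared DMRs between discovery and validation")
  d <- logitLikeTransform(discovery[shared, , drop = FALSE])
  v <- logitLikeTransform(validation[shared, , drop = FALSE])
  v <- quantileNormalizeToTarget(v, as.vector(d))
  combined <- cbind(d, v)
  batch <- c(rep("discovery", ncol(d)), rep("validation", ncol(v)))
  adj <- combatAdjust(combined, batch)
  list(discovery = backTransform(adj[, seq_len(ncol(d)), drop = FALSE]),
       validation = backTransform(adj[, ncol(d) + seq_len(ncol(v)), drop = FALSE]),
       shared = shared)
}

#' Concordance between discovery and validation effect sizes
#'
#' Compares per-DMR mean methylation differences (condition minus healthy
#' control, percentage points) between cohorts: Pearson correlation plus
#' counts of DMRs that (a) are significant in the validation cohort at the
#' q-value cutoff, (b) are significant with the same effect direction as
#' discovery, and (c) additionally pass the absolute difference cutoff.
#'
#' @param discoveryDiffs,validationDiffs paired numeric vectors of per-DMR
#'   mean differences.
#' @param validationQ optional per-DMR q-values in the validation cohort;
#'   when omitted, counts (a)-(c) are computed without the significance
#'   filter.
#' @param qCutoff q-value cutoff (default 0.01).
#' @param diffCutoff absolute-difference cutoff in percentage points
#'   (default 25).
#' @return list with `pearson_r`, `n`, `n_significant`, `n_same_sign`,
#'   `n_validated`.
#' @export
concordanceReport <- function(discoveryDiffs, validationDiffs,
                              validationQ = NULL, qCutoff = 0.01,
                              diffCutoff = 25) {
  if (length(discoveryDiffs) != length(validationDiffs))
    stop("difference vectors must have equal length")
  sig <- if (is.null(validationQ)) rep(TRUE, length(validationDiffs))
         else validationQ <= qCutoff
  sameSign <- sig & sign(validationDiffs) == sign(discoveryDiffs) &
    discoveryDiffs != 0
  validated <- sameSign & abs(validationDiffs) >= diffCutoff
  list(pearson_r = stats::cor(discoveryDiffs, validationDiffs,
                              use = "complete.obs"),
       n = length(discoveryDiffs),
       n_significant = sum(sig, na.rm = TRUE),
       n_same_sign = sum(sameSign, na.rm = TRUE),
       n_validated = sum(validated, na.rm = TRUE))
}
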
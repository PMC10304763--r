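#' Simulate bulk mixtures with known cell-type proportions
#'
#' Draws per-sample cell-type proportions from a flat Dirichlet over the
#' atlas cell types (unless explicit proportions are given), forms each bulk
#' profile as `atlas %*% p` plus optional additive Gaussian noise, and clips
#' to \[0, 1\]. Used to benchmark deconvolution models against known truth.
#'
#' @param atlas pooled [MethylationAtlas-class] without missing values.
#' @param nSamples number of mixtures to simulate.
#' @param proportions optional matrix (samples x cell types, rows summing to
#'   1 within 1e-6) of explicit mixing proportions; overrides `nSamples`.
#' @param noiseSD standard deviation of additive Gaussian noise on the beta
#'   scale (default 0).
#' @param seed integer seed.
#' @return list with `profiles` (probe x sample beta matrix),
#'   `proportions` (sample x cell-type matrix of the true mixing weights),
#'   `noiseSD` and `seed`.
#' @export
simulateCellMix <- function(atlas, nSamples = 100L, proportions = NULL,
                            noiseSD = 0, seed = 1L) {
  b <- betaValues(atlas)
  if (anyNA(b)) stop("atlas must be pooled and complete")
  stopifnot(noiseSD >= 0)
  set.seed(seed)
  k <- ncol(b)
  if (is.null(proportions)) {
    proportions <- rdirichlet(nSamples, rep(1, k))
  } else {
    proportions <- as.matrix(proportions)
    if (ncol(proportions) != k)
      stop("proportions must have one column per atlas cell type")
    if (any(abs(rowSums(proportions) - 1) > 1e-6))
      stop("explicit proportions must sum to 1 (within 1e-6) per sample")
    nSamples <- nrow(proportions)
  }
  colnames(proportions) <- colnames(b)
  rownames(proportions) <- sprintf("mix%03d", seq_len(nSamples))
  profiles <- b %*% t(proportions)
  if (noiseSD > 0)
    profiles <- profiles + stats::rnorm(length(profiles), 0, noiseSD)
  profiles <- clip01(profiles)
  colnames(profiles) <- rownames(proportions)
  list(profiles = profiles, proportions = proportions,
       noiseSD = noiseSD, seed = seed)
}

#' Benchmark deconvolution models on simulated mixtures by RMSE
#'
#' Deconvolutes every simulated mixture with each requested model and
#' reports, per model, the root-mean-square error between predicted and true
#' proportions, pooled over all (sample, cell type) entries. Models are
#' returned ranked by ascending RMSE.
#'
#' @param mixtures value of [simulateCellMix()].
#' @param signature a [SignatureMatrix-class] or [MethylationAtlas-class].
#' @param models character vector of model names (default all four).
#' @param minProbes see [deconvolute()].
#' @return list with `rmse` (named, sorted ascending), `n_samples`,
#'   `failures` (per-model count of samples excluded due to solver failure),
#'   `predictions` (per-model sample x cell-type matrices) and `seed`.
#' @export
benchmarkModels <- function(mixtures, signature,
                            models = c("nnls", "svr", "qp", "rlm"),
                            minProbes = NULL) {
  truth <- mixtures$proportions
  if (!nrow(truth)) stop("no mixtures to benchmark")
  bulks <- lapply(seq_len(ncol(mixtures$profiles)), function(j) {
    stats::setNames(mixtures$profiles[, j], rownames(mixtures$profiles))
  })
  names(bulks) <- colnames(mixtures$profiles)
  cts <- cellTypes(signature)
  rmse <- numeric(0); failures <- integer(0); preds <- list()
  for (m in models) {
    run <- deconvoluteCohort(bulks, signature, model = m, minProbes = minProbes)
    failures[m] <- length(run$failures)
    pm <- proportionMatrix(run, signature)
    ok <- intersect(rownames(pm), rownames(truth))
    err <- pm[ok, cts, drop = FALSE] - truth[ok, cts, drop = FALSE]
    rmse[m] <- sqrt(mean(err^2))
    preds[[m]] <- pm
  }
  list(rmse = sort(rmse), n_samples = nrow(truth), failures = failures,
       predictions = preds, seed = mixtures$seed)
}
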
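#' Specification of a synthetic ccfDNA cohort
#'
#' Bundles the study-design parameters of the synthetic WGBS cohort
#' generator. Defaults mirror the discovery-cohort design: 8 healthy
#' controls, 8 STEMI, 7 NSTEMI and 6 UA patients, elevated ccfDNA levels in
#' the ACS groups, planted group-specific DMRs at a 40-percentage-point
#' effect and severity-linear windows.
#'
#' @param groupSizes named integer vector of samples per group.
#' @param nPlantedDMRs planted DMR windows per ACS group (default 10).
#' @param delta planted methylation effect in percentage points (default 40).
#' @param nSeverityWindows windows whose methylation tracks severity
#'   linearly (default 10).
#' @param severitySlope beta-scale methylation shift per severity unit in the
#'   severity-linear windows (default 0.05, i.e. 5 pp per severity step).
#' @param ccfdnaMeanlog named numeric vector: lognormal meanlog of the
#'   ccfDNA level (ng per ml plasma) per group. Defaults put controls near
#'   6 ng/ml and ACS groups at 20-30 ng/ml, within the range reported for
#'   ACS plasma.
#' @param ccfdnaSdlog lognormal sdlog (default 0.3).
#' @param coverageLambda Poisson mean of per-CpG read coverage minus one
#'   (coverage ~ Poisson(lambda) + 1; default 8, matching a mean WGBS
#'   coverage of ~9x).
#' @param seed mandatory integer seed.
#' @return A named list with class `"CohortSpec"`.
#' @export
cohortSpec <- function(groupSizes = c(control = 8L, STEMI = 8L,
                                      NSTEMI = 7L, UA = 6L),
                       nPlantedDMRs = 10L, delta = 40,
                       nSeverityWindows = 10L, severitySlope = 0.05,
                       ccfdnaMeanlog = c(control = log(6), UA = log(20),
                                         NSTEMI = log(25), STEMI = log(30)),
                       ccfdnaSdlog = 0.3, coverageLambda = 8, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(groupSizes >= 1), delta > 0, delta <= 100)
  structure(list(groupSizes = groupSizes, nPlantedDMRs = as.integer(nPlantedDMRs),
                 delta = delta, nSeverityWindows = as.integer(nSeverityWindows),
                 severitySlope = severitySlope, ccfdnaMeanlog = ccfdnaMeanlog,
                 ccfdnaSdlog = ccfdnaSdlog, coverageLambda = coverageLambda,
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Generate a synthetic methylation atlas with planted cell-type markers
#'
#' Background betas are drawn from Beta(5, 5) (centered at 0.5). Each cell
#' type receives two disjoint marker blocks: hypermethylated probes at `0.5 +
#' contrast/2` in the target type and `0.5 - contrast/2` elsewhere, and
#' hypomethylated probes with the pattern reversed; `contrast = 1` yields
#' exactly one-hot marker rows against a 0.5 background. Probe coordinates
#' are placed on one synthetic chromosome with 100-bp spacing.
#'
#' @param nCellTypes number of cell types (default 10; the first types get
#'   plasma-relevant labels such as Neutrophil, Monocyte, ...).
#' @param nCpGs number of probes (default 5000).
#' @param nMarkersPerType markers per direction per cell type (default 10).
#' @param markerContrast beta contrast of markers in (0, 1\] (default 0.9).
#' @param seed integer seed.
#' @return list with `atlas` (a [MethylationAtlas-class] with coordinates)
#'   and `truth` (data.frame `probe_id`, `cell_type`, `direction`).
#' @export
makeSyntheticAtlas <- function(nCellTypes = 10L, nCpGs = 5000L,
                               nMarkersPerType = 10L, markerContrast = 0.9,
                               seed = 1L) {
  baseNames <- c("Neutrophil", "Monocyte", "CD4T", "CD8T", "NK", "Bcell",
                 "Erythroblast", "Hepatocyte", "HeartLV", "VascEndothelial",
                 "Kidney", "Lung", "Adipose", "CorticalNeuron", "Pancreas")
  if (nCellTypes > length(baseNames))
    baseNames <- c(baseNames, sprintf("Tissue%02d", seq_len(nCellTypes)))
  cts <- baseNames[seq_len(nCellTypes)]
  nMarkers <- 2L * nMarkersPerType * nCellTypes
  if (nMarkers > nCpGs) stop("infeasible block allocation: too many markers for nCpGs")
  set.seed(seed)
  probes <- sprintf("cg%08d", seq_len(nCpGs))
  b <- matrix(stats::rbeta(nCpGs * nCellTypes, 5, 5), nCpGs, nCellTypes,
              dimnames = list(probes, cts))
  hi <- 0.5 + markerContrast / 2
  lo <- 0.5 - markerContrast / 2
  # spread marker rows evenly over the chromosome so they do not pile into
  # a handful of 500-bp windows
  markerIdx <- round(seq(1, nCpGs, length.out = nMarkers))
  markerIdx <- unique(markerIdx)
  stopifnot(length(markerIdx) == nMarkers)
  truth <- data.frame(probe_id = probes[markerIdx],
                      cell_type = rep(cts, each = 2L * nMarkersPerType),
                      direction = rep(rep(c("hyper", "hypo"),
                                          each = nMarkersPerType), nCellTypes),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(truth))) {
    row <- markerIdx[i]
    if (truth$direction[i] == "hyper") {
      b[row, ] <- lo; b[row, truth$cell_type[i]] <- hi
    } else {
      b[row, ] <- hi; b[row, truth$cell_type[i]] <- lo
    }
  }
  coords <- data.frame(probe_id = probes, chrom = "chrS",
                       pos = 1L + (seq_len(nCpGs) - 1L) * 100L, strand = "+",
                       stringsAsFactors = FALSE)
  list(atlas = MethylationAtlas(b, coords), truth = truth)
}

#' Default group mixing proportions for synthetic cohorts
#'
#' Healthy baseline gives the first atlas cell type (neutrophils in the
#' default atlas) a 30% share with the remainder spread evenly; the ACS
#' groups raise that share by 5 percentage points per severity unit before
#' renormalization, mimicking the elevated neutrophil contribution seen in
#' ACS plasma.
#'
#' @param atlas a [MethylationAtlas-class].
#' @return matrix of proportions, rows `control`, `UA`, `NSTEMI`, `STEMI`.
#' @export
defaultGroupProportions <- function(atlas) {
  cts <- cellTypes(atlas)
  k <- length(cts)
  base <- rep((1 - 0.30) / (k - 1), k)
  names(base) <- cts
  base[1] <- 0.30
  sev <- c(control = 0, UA = 1, NSTEMI = 2, STEMI = 3)
  out <- sapply(names(sev), function(g) {
    p <- base
    p[1] <- base[1] + 0.05 * sev[[g]]
    p / sum(p)
  })
  t(out)  # groups x cell types
}

#' Simulate a WGBS ccfDNA cohort with known structure
#'
#' Each sample's probe-level beta profile is the atlas mixed by its group's
#' cell-type proportions; planted DMR windows shift the beta by +/- delta in
#' the target ACS group, severity-linear windows shift it by `severitySlope *
#' severity`; read counts are then drawn per CpG as `coverage ~
#' Poisson(lambda) + 1` and `methylated ~ Binomial(coverage, beta)`. ccfDNA
#' levels are drawn lognormally per group (elevated in ACS). Clinical markers
#' (troponin_t, ck, lvef, crp) are generated with severity-linked means so
#' marker models have signal.
#'
#' @param spec a [cohortSpec()].
#' @param atlas a [MethylationAtlas-class] with coordinates (e.g. from
#'   [makeSyntheticAtlas()]).
#' @param trueProportions optional group x cell-type proportion matrix
#'   (rows `control`, `UA`, `NSTEMI`, `STEMI`); default raises the first
#'   cell type with severity.
#' @param window tile width used to define planted windows (default 500).
#' @param excludeProbes probes never used for planted windows (e.g. atlas
#'   marker probes, so deconvolution and DMR truths stay independent).
#' @param truth optional `truth` element of a previous cohort: reuses its
#'   planted DMR windows, severity windows and slope, so an independent
#'   cohort (e.g. a validation cohort) carries the same biological signal.
#' @return list with `calls` (list of [MethylationCallSet-class]), `sheet`
#'   (sample sheet data.frame), `trueBeta` (probe x sample matrix of the
#'   noise-free betas) and `truth` (planted DMR windows, severity windows,
#'   group proportions).
#' @export
simulateWGBSCohort <- function(spec, atlas, trueProportions = NULL,
                               window = 500L, excludeProbes = NULL,
                               truth = NULL) {
  stopifnot(inherits(spec, "CohortSpec"))
  coords <- probeCoords(atlas)
  if (is.null(coords)) stop("atlas must have probe coordinates")
  b <- betaValues(atlas)
  if (anyNA(b)) stop("atlas must be complete")
  if (is.null(trueProportions)) trueProportions <- defaultGroupProportions(atlas)
  groups <- names(spec$groupSizes)
  stopifnot(all(groups %in% rownames(trueProportions)))
  set.seed(deriveSeed(spec$seed, "wgbs_cohort"))

  probes <- probeIDs(atlas)
  chrom <- as.character(GenomicRanges::seqnames(coords[probes]))
  pos <- GenomicRanges::start(coords[probes])
  winKey <- paste0(chrom, ":", (pos - 1L) %/% window * window + 1L)
  eligible <- unique(winKey[!(probes %in% (excludeProbes %||% character(0)))])
  # windows containing excluded probes are not planted on at all
  tainted <- unique(winKey[probes %in% (excludeProbes %||% character(0))])
  eligible <- setdiff(eligible, tainted)
  acs <- setdiff(groups, "control")
  if (!is.null(truth)) {
    dmrTruth <- truth$dmrs
    sevWindows <- truth$severityWindows
    spec$severitySlope <- truth$severitySlope
  } else {
    nNeed <- length(acs) * spec$nPlantedDMRs + spec$nSeverityWindows
    if (nNeed > length(eligible))
      stop("not enough windows to plant DMRs; increase atlas size")
    planted <- sample(eligible, nNeed)
    dmrTruth <- data.frame(
      window = planted[seq_len(length(acs) * spec$nPlantedDMRs)],
      group = rep(acs, each = spec$nPlantedDMRs),
      direction = rep_len(c("hyper", "hypo"), length(acs) * spec$nPlantedDMRs),
      delta = spec$delta, stringsAsFactors = FALSE
    )
    sevWindows <- planted[length(acs) * spec$nPlantedDMRs + seq_len(spec$nSeverityWindows)]
  }

  sev <- c(control = 0, UA = 1, NSTEMI = 2, STEMI = 3)
  samples <- unlist(lapply(groups, function(g)
    sprintf("%s_%02d", g, seq_len(spec$groupSizes[[g]]))))
  groupOf <- rep(groups, times = spec$groupSizes[groups])
  names(groupOf) <- samples

  trueBeta <- matrix(NA_real_, length(probes), length(samples),
                     dimnames = list(probes, samples))
  calls <- vector("list", length(samples))
  names(calls) <- samples
  for (s in samples) {
    g <- groupOf[[s]]
    beta <- as.vector(b %*% trueProportions[g, colnames(b)])
    for (i in seq_len(nrow(dmrTruth))) {
      if (dmrTruth$group[i] != g) next
      inWin <- winKey == dmrTruth$window[i]
      shift <- (dmrTruth$delta[i] / 100) * ifelse(dmrTruth$direction[i] == "hyper", 1, -1)
      beta[inWin] <- beta[inWin] + shift
    }
    if (sev[[g]] > 0) {
      inSev <- winKey %in% sevWindows
      beta[inSev] <- beta[inSev] + spec$severitySlope * sev[[g]]
    }
    beta <- clip01(beta)
    trueBeta[, s] <- beta
    cov <- stats::rpois(length(beta), spec$coverageLambda) + 1L
    meth <- stats::rbinom(length(beta), cov, beta)
    calls[[s]] <- MethylationCallSet(s, data.frame(
      chrom = chrom, pos = pos, strand = "+", meth = meth, cov = cov,
      stringsAsFactors = FALSE))
  }
  ccf <- stats::rlnorm(length(samples),
                       meanlog = spec$ccfdnaMeanlog[groupOf],
                       sdlog = spec$ccfdnaSdlog)
  sevCode <- sev[groupOf]
  sheet <- data.frame(
    sample = samples, group = groupOf,
    ccfdna_ng_per_ml = round(ccf, 2), batch = "discovery",
    troponin_t = round(pmax(0, 5 + 30 * sevCode + stats::rnorm(length(samples), 0, 15)), 2),
    ck = round(pmax(0, 100 + 150 * sevCode + stats::rnorm(length(samples), 0, 120)), 1),
    lvef = round(pmin(80, pmax(25, 70 - 4 * sevCode + stats::rnorm(length(samples), 0, 4))), 1),
    crp = round(pmax(0, 2 + 3 * sevCode + stats::rnorm(length(samples), 0, 3)), 2),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(calls = calls, sheet = sheet, trueBeta = trueBeta,
       truth = list(dmrs = dmrTruth, severityWindows = sevWindows,
                    severitySlope = spec$severitySlope,
                    proportions = trueProportions[groups, , drop = FALSE],
                    window = window))
}

#' Simulate a targeted-sequencing panel with batch effects
#'
#' Restricts a cohort to the CpGs of a panel (a set of windows and/or
#' probes), applies a location/scale distortion on the pseudo-count log
#' scale (`t' = scale * t + shift`, see [logitLikeTransform()]) emulating the
#' systematic bias of a different sequencing chemistry, and independently
#' resamples read counts.
#'
#' @param cohort value of [simulateWGBSCohort()] (its `trueBeta` and `calls`
#'   provide the per-sample methylation states).
#' @param panelWindows character vector of window keys (`chrom:start`) or
#'   `NULL` for all windows.
#' @param batchShift additive shift on the transformed scale (default 1).
#' @param batchScale multiplicative scale on the transformed scale (default 1).
#' @param coverageLambda Poisson coverage mean for the resampled reads
#'   (default 30; targeted panels sequence deeper than WGBS).
#' @param seed integer seed.
#' @return list with `calls` (per-sample [MethylationCallSet-class] restricted
#'   to the panel) and `sheet` (the cohort sheet with `batch =
#'   "validation"`).
#' @export
simulateTargetedPanel <- function(cohort, panelWindows = NULL,
                                  batchShift = 1, batchScale = 1,
                                  coverageLambda = 30, seed = 1L) {
  set.seed(deriveSeed(seed, "targeted_panel"))
  tb <- cohort$trueBeta
  anyCalls <- cohort$calls[[1]]
  cl <- methCalls(anyCalls)
  window <- cohort$truth$window %||% 500L
  winKey <- paste0(cl$chrom, ":", (cl$pos - 1L) %/% window * window + 1L)
  keep <- if (is.null(panelWindows)) rep(TRUE, nrow(cl)) else winKey %in% panelWindows
  if (!any(keep)) stop("panel is empty after restriction")
  pct <- 100 * tb[keep, , drop = FALSE]
  t <- logitLikeTransform(pct)
  t <- batchScale * t + batchShift
  beta2 <- backTransform(t) / 100
  calls <- lapply(colnames(tb), function(s) {
    cov <- stats::rpois(nrow(beta2), coverageLambda) + 1L
    meth <- stats::rbinom(nrow(beta2), cov, beta2[, s])
    MethylationCallSet(s, data.frame(
      chrom = cl$chrom[keep], pos = cl$pos[keep], strand = "+",
      meth = meth, cov = cov, stringsAsFactors = FALSE))
  })
  names(calls) <- colnames(tb)
  sheet <- cohort$sheet
  sheet$batch <- "validation"
  list(calls = calls, sheet = sheet)
}
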
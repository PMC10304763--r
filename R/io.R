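#' Read per-CpG methylation calls
#'
#' Supports two dialects. `"bismark_cov"` is the Bismark coverage format
#' (TSV, no header: chrom, start, end, methylation %, count methylated,
#' count unmethylated) with 1-based positions. `"bedgraph"` is the
#' MethylDackel-style bedGraph (chrom, 0-based start, end, methylation %,
#' count methylated, count unmethylated); its 0-based half-open starts are
#' converted to 1-based positions on input. When the stated methylation
#' percentage disagrees with the counts by more than one unit the counts win,
#' with a warning. Malformed lines are reported with their line numbers.
#'
#' @param path input file.
#' @param dialect `"bismark_cov"` (default) or `"bedgraph"`.
#' @param sampleID sample label; default is the file name without extension.
#' @param strand strand to assign to the records (callers emitting these
#'   formats have usually already destranded; default `"+"`).
#' @return A [MethylationCallSet-class].
#' @export
readCalls <- function(path, dialect = c("bismark_cov", "bedgraph"),
                      sampleID = NULL, strand = "+") {
  dialect <- match.arg(dialect)
  sampleID <- sampleID %||% sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "pct",
                                        "meth", "unmeth"))
  bad <- which(is.na(df$start) | is.na(df$meth) | is.na(df$unmeth))
  if (length(bad))
    stop("malformed lines: ", paste(utils::head(bad, 10), collapse = ", "))
  if (any(df$meth < 0 | df$unmeth < 0)) stop("negative counts in ", path)
  pos <- if (dialect == "bedgraph") df$start + 1L else df$start
  cov <- df$meth + df$unmeth
  stated <- df$pct
  implied <- ifelse(cov > 0, 100 * df$meth / cov, NA)
  off <- abs(stated - implied) > 1 & !is.na(implied)
  if (any(off, na.rm = TRUE))
    warning(sprintf("%d lines with methylation %% inconsistent with counts; counts win",
                    sum(off, na.rm = TRUE)))
  MethylationCallSet(sampleID, data.frame(
    chrom = df$chrom, pos = pos, strand = strand,
    meth = df$meth, cov = cov, stringsAsFactors = FALSE))
}

#' Write methylation calls
#'
#' @param calls a [MethylationCallSet-class].
#' @param path output file.
#' @param dialect output dialect (see [readCalls()]).
#' @return invisibly, `path`.
#' @export
writeCalls <- function(calls, path, dialect = c("bismark_cov", "bedgraph")) {
  dialect <- match.arg(dialect)
  cl <- methCalls(calls)
  start <- if (dialect == "bedgraph") cl$pos - 1L else cl$pos
  end <- if (dialect == "bedgraph") cl$pos else cl$pos
  pct <- ifelse(cl$cov > 0, round(100 * cl$meth / cl$cov, 6), 0)
  out <- data.frame(cl$chrom, start, end, pct, cl$meth, cl$cov - cl$meth)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' CSV with at least `sample` and `group` columns; typically also
#' `ccfdna_ng_per_ml`, `batch` and clinical marker columns.
#'
#' @param path CSV file.
#' @param required columns that must be present.
#' @return data.frame.
#' @export
readSampleSheet <- function(path, required = c("sample", "group")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("sample sheet misses column(s): ", paste(missing, collapse = ", "))
  df
}

#' Pipeline configuration
#'
#' Collects the parameters of the end-to-end synthetic workflows. All
#' randomness flows from the single `seed`; stage seeds are derived from it
#' deterministically.
#'
#' @param seed global integer seed (mandatory).
#' @param outDir output directory (`NULL` for no file output).
#' @param nCellTypes,nCpGs,nMarkersPerType,markerContrast synthetic atlas
#'   parameters (see [makeSyntheticAtlas()]).
#' @param spec a [cohortSpec()]; default uses the global seed.
#' @param validationGroupSizes validation-cohort group sizes (default
#'   2/4/3/2 for control/STEMI/NSTEMI/UA).
#' @param batchShift,batchScale targeted-panel distortion on the transformed
#'   scale.
#' @param qCutoff,diffCutoff DMR calling thresholds.
#' @param cvFolds,cvRepeats classifier cross-validation design.
#' @return named list with class `"RunConfig"`.
#' @export
pipelineConfig <- function(seed, outDir = NULL,
                           nCellTypes = 10L, nCpGs = 5000L,
                           nMarkersPerType = 10L, markerContrast = 0.9,
                           spec = NULL,
                           validationGroupSizes = c(control = 2L, STEMI = 4L,
                                                    NSTEMI = 3L, UA = 2L),
                           batchShift = 1, batchScale = 1,
                           qCutoff = 0.01, diffCutoff = 25,
                           cvFolds = 10L, cvRepeats = 10L) {
  if (missing(seed)) stop("seed is mandatory")
  spec <- spec %||% cohortSpec(seed = deriveSeed(seed, "spec"))
  structure(list(seed = as.integer(seed), outDir = outDir,
                 nCellTypes = nCellTypes, nCpGs = nCpGs,
                 nMarkersPerType = nMarkersPerType,
                 markerContrast = markerContrast, spec = spec,
                 validationGroupSizes = validationGroupSizes,
                 batchShift = batchShift, batchScale = batchScale,
                 qCutoff = qCutoff, diffCutoff = diffCutoff,
                 cvFolds = cvFolds, cvRepeats = cvRepeats),
            class = "RunConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.out_path <- function(config, file) {
  if (is.null(config$outDir)) return(NULL)
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  file.path(config$outDir, file)
}

#' Run an end-to-end workflow on synthetic data
#'
#' `workflow = "discovery"`: generates the synthetic atlas and WGBS cohort,
#' builds the signature, maps calls to probes and deconvolutes every sample
#' (NNLS), tiles the genome and calls DMRs per ACS group versus control,
#' fits severity models on the DMR methylation matrix with the ccfDNA
#' covariate, selects severity-associated DMRs, embeds samples by PCA and
#' trains the ACS classifiers. `workflow = "validation"`: simulates an
#' independent targeted cohort with a batch effect, normalizes it onto the
#' discovery scale, and reports per-group effect-size concordance, a combined
#' PCA and external classifier accuracy. `workflow = "benchmark"`: simulates
#' mixtures from the atlas and benchmarks the four deconvolution models by
#' RMSE.
#'
#' Artifacts (proportion TSV, DMR BED/TSV, severity TSV, metrics JSON and a
#' parameter manifest) are written under `config$outDir` when set.
#'
#' @param config a [pipelineConfig()].
#' @param workflow one of `"discovery"`, `"validation"`, `"benchmark"`.
#' @param discovery for `workflow = "validation"`: the result of a previous
#'   discovery run (it is computed on the fly when omitted).
#' @return a report list; see details of each workflow above.
#' @export
runPipeline <- function(config, workflow = c("discovery", "validation",
                                             "benchmark"),
                        discovery = NULL) {
  workflow <- match.arg(workflow)
  stopifnot(inherits(config, "RunConfig"))
  synth <- .stage("synth", {
    makeSyntheticAtlas(config$nCellTypes, config$nCpGs,
                       config$nMarkersPerType, config$markerContrast,
                       seed = deriveSeed(config$seed, "atlas"))
  })
  if (workflow == "benchmark") return(.run_benchmark(config, synth))
  if (workflow == "discovery") return(.run_discovery(config, synth))
  if (is.null(discovery)) discovery <- .run_discovery(config, synth)
  .run_validation(config, synth, discovery)
}

.run_benchmark <- function(config, synth) {
  sig <- .stage("signature", buildSignatureMatrix(
    synth$atlas, selectionConfig(kTop = config$nMarkersPerType, kDiff = 20)))
  mix <- .stage("simulate-mix", simulateCellMix(
    synth$atlas, nSamples = 200L, noiseSD = 0.05,
    seed = deriveSeed(config$seed, "mix")))
  bench <- .stage("benchmark", benchmarkModels(mix, sig))
  .write_json(config, "benchmark.json",
              list(rmse = as.list(bench$rmse), n_samples = bench$n_samples))
  list(signature = sig, mixtures = mix, benchmark = bench)
}

.run_discovery <- function(config, synth) {
  sig <- .stage("signature", buildSignatureMatrix(
    synth$atlas, selectionConfig(kTop = config$nMarkersPerType, kDiff = 20)))
  cohort <- .stage("cohort", simulateWGBSCohort(
    config$spec, synth$atlas, excludeProbes = synth$truth$probe_id))
  manifest <- .manifest_from_atlas(synth$atlas)
  bulks <- .stage("map-probes", lapply(cohort$calls, function(cs)
    mapToProbes(collapseStrands(cs), manifest)))
  decon <- .stage("deconvolute",
                  deconvoluteCohort(bulks, sig, model = "nnls"))
  tiles <- .stage("tile", tileCounts(cohort$calls))
  groups <- split(cohort$sheet$sample, cohort$sheet$group)
  acs <- setdiff(names(groups), "control")
  dmrSets <- list()
  tests <- list()
  for (g in acs) {
    tst <- .stage("dm-test", dmTest(tiles, groups[[g]], groups$control))
    tst$q_value <- adjustQvalues(tst$p_value)
    tests[[g]] <- tst
    dmrSets[[g]] <- callDMRs(tst, config$qCutoff, config$diffCutoff)
  }
  allDMRs <- unique(do.call(rbind, lapply(dmrSets, function(d)
    d[, c("chrom", "start", "end")])))
  mm <- methylationMatrix(tiles, allDMRs)
  sheet <- cohort$sheet[match(colnames(mm), cohort$sheet$sample), ]
  sev <- encodeSeverity(sheet$group, includeControls = FALSE)
  fits <- .stage("severity", fitSeverityModels(mm, sev, sheet$ccfdna_ng_per_ml))
  assoc <- selectAssociatedDMRs(fits, alpha = 0.05)
  selDMRs <- assoc$selected$dmr
  pcaM <- t(mm[selDMRs, , drop = FALSE])
  pcaM <- pcaM[, colSums(is.na(pcaM)) == 0, drop = FALSE]
  pca <- .stage("pca", pcaEmbed(pcaM))
  sil <- meanSilhouette(pca$coords, sheet$group)
  clf <- .stage("classify", trainACSClassifiers(
    pcaM, sheet$group, trainFrac = 0.7, cvFolds = config$cvFolds,
    cvRepeats = config$cvRepeats, seed = deriveSeed(config$seed, "clf")))
  # artifacts
  if (!is.null(config$outDir)) {
    utils::write.table(decon$long, .out_path(config, "proportions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (g in acs)
      writeDMRs(dmrSets[[g]],
                .out_path(config, sprintf("dmrs_%s.bed", g)),
                .out_path(config, sprintf("dmrs_%s.tsv", g)))
    utils::write.table(fits, .out_path(config, "severity_fits.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_json(config, "discovery_metrics.json", list(
      n_dmrs = vapply(dmrSets, nrow, 1L),
      severity_associated = nrow(assoc$selected),
      severity_fraction_pct = assoc$fraction,
      pca_mean_silhouette = sil,
      classifier_test_accuracy = lapply(
        clf[intersect(names(clf), c("rf", "pls", "pmr"))],
        function(x) x$test_accuracy)
    ))
    .write_manifest(config, "discovery")
  }
  list(atlas = synth, signature = sig, cohort = cohort,
       deconvolution = decon, tiles = tiles, tests = tests,
       dmrs = dmrSets, severityFits = fits, associated = assoc,
       pca = pca, silhouette = sil, classifiers = clf, sheet = sheet,
       methylation = mm)
}

.run_validation <- function(config, synth, discovery) {
  spec2 <- cohortSpec(groupSizes = config$validationGroupSizes,
                      nPlantedDMRs = config$spec$nPlantedDMRs,
                      delta = config$spec$delta,
                      nSeverityWindows = config$spec$nSeverityWindows,
                      severitySlope = config$spec$severitySlope,
                      coverageLambda = config$spec$coverageLambda,
                      seed = deriveSeed(config$seed, "validation_cohort"))
  valCohort <- .stage("validation-cohort", simulateWGBSCohort(
    spec2, synth$atlas, excludeProbes = synth$truth$probe_id,
    truth = discovery$cohort$truth))
  # same planted windows as discovery are not guaranteed; restrict the panel
  # to the discovery DMR windows so both cohorts measure the same regions
  allDMRs <- unique(do.call(rbind, lapply(discovery$dmrs, function(d)
    d[, c("chrom", "start", "end")])))
  panelKeys <- paste0(allDMRs$chrom, ":", allDMRs$start)
  panel <- .stage("panel", simulateTargetedPanel(
    valCohort, panelWindows = panelKeys, batchShift = config$batchShift,
    batchScale = config$batchScale,
    seed = deriveSeed(config$seed, "panel")))
  valTiles <- .stage("tile-validation", tileCounts(panel$calls))
  valMM <- methylationMatrix(valTiles, allDMRs)
  discMM <- discovery$methylation
  norm <- .stage("normalize", normalizeValidationCohort(discMM, valMM))
  # per-group effect-size concordance on the shared DMRs
  discSheet <- discovery$sheet
  valSheet <- panel$sheet
  concord <- list()
  for (g in setdiff(unique(discSheet$group), "control")) {
    dd <- rowMeans(norm$discovery[, discSheet$group == g, drop = FALSE],
                   na.rm = TRUE) -
      rowMeans(norm$discovery[, discSheet$group == "control", drop = FALSE],
               na.rm = TRUE)
    vd <- rowMeans(norm$validation[, valSheet$group == g, drop = FALSE],
                   na.rm = TRUE) -
      rowMeans(norm$validation[, valSheet$group == "control", drop = FALSE],
               na.rm = TRUE)
    ok <- is.finite(dd) & is.finite(vd)
    concord[[g]] <- concordanceReport(dd[ok], vd[ok])
  }
  combined <- cbind(norm$discovery, norm$validation)
  okRows <- rowSums(is.na(combined)) == 0
  pca <- .stage("pca-combined", pcaEmbed(t(combined[okRows, , drop = FALSE])))
  ext <- NULL
  selDMRs <- intersect(discovery$associated$selected$dmr, rownames(combined))
  if (length(selDMRs) >= 2) {
    feat <- t(norm$discovery[selDMRs, , drop = FALSE])
    featOK <- colSums(is.na(feat)) == 0
    extFeat <- t(norm$validation[selDMRs, , drop = FALSE])
    ext <- .stage("classify-external", trainACSClassifiers(
      feat[, featOK, drop = FALSE], discSheet$group,
      cvFolds = config$cvFolds, cvRepeats = config$cvRepeats,
      seed = deriveSeed(config$seed, "clf_ext"),
      external = list(features = extFeat[, featOK, drop = FALSE],
                      labels = valSheet$group)))
  }
  if (!is.null(config$outDir)) {
    .write_json(config, "validation_metrics.json", list(
      concordance = lapply(concord, function(x) x[c("pearson_r", "n",
                                                    "n_same_sign")]),
      external_accuracy = if (!is.null(ext)) lapply(
        ext[intersect(names(ext), c("rf", "pls", "pmr"))],
        function(x) x$external_accuracy)
    ))
    .write_manifest(config, "validation")
  }
  list(cohort = valCohort, panel = panel, normalized = norm,
       concordance = concord, pca = pca, external = ext)
}

.manifest_from_atlas <- function(atlas) {
  coords <- probeCoords(atlas)
  data.frame(probe_id = names(coords),
             chrom = as.character(GenomicRanges::seqnames(coords)),
             pos = GenomicRanges::start(coords), strand = "+",
             stringsAsFactors = FALSE)
}

.write_json <- function(config, file, x) {
  p <- .out_path(config, file)
  if (!is.null(p))
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(p)
}

.write_manifest <- function(config, workflow) {
  p <- .out_path(config, sprintf("run_manifest_%s.json", workflow))
  if (is.null(p)) return(invisible(NULL))
  cfg <- unclass(config)
  cfg$spec <- unclass(cfg$spec)
  jsonlite::write_json(list(workflow = workflow, config = cfg),
                       p, auto_unbox = TRUE, pretty = TRUE)
  invisible(p)
}

#' Read a pipeline configuration from YAML
#'
#' Reads a YAML file whose keys mirror the [pipelineConfig()] arguments
#' (nested `spec:` keys mirror [cohortSpec()]).
#'
#' @param path YAML file.
#' @return A `"RunConfig"` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$seed)) stop("config must set a seed")
  spec <- NULL
  if (!is.null(y$spec)) {
    sa <- y$spec
    if (!is.null(sa$groupSizes)) sa$groupSizes <- unlist(sa$groupSizes)
    if (!is.null(sa$ccfdnaMeanlog)) sa$ccfdnaMeanlog <- unlist(sa$ccfdnaMeanlog)
    sa$seed <- sa$seed %||% deriveSeed(y$seed, "spec")
    spec <- do.call(cohortSpec, sa)
  }
  args <- y[setdiff(names(y), "spec")]
  if (!is.null(args$validationGroupSizes))
    args$validationGroupSizes <- unlist(args$validationGroupSizes)
  args$spec <- spec
  do.call(pipelineConfig, args)
}
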
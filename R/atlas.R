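#' Selection configuration for signature construction
#'
#' Bundles the tunable parameters of tissue-specific CpG selection.
#'
#' @param kTop probes per direction (hyper-/hypomethylated) per cell type
#'   selected from the row-scaled atlas (default 100).
#' @param kDiff most-differential probes per cell type from the unscaled
#'   atlas (default 200).
#' @param neighborWindow distance in bp within which neighboring atlas CpGs
#'   are pulled into the signature (default 50).
#' @param varianceThreshold minimum row-wise population variance of beta
#'   values; rows below it are dropped before selection (default 0.001,
#'   i.e. 0.1% on the beta scale).
#' @param kPair pairwise-specific probes added per unordered cell-type pair
#'   (default 1).
#' @return A named list with class `"SelectionConfig"`.
#' @export
selectionConfig <- function(kTop = 100L, kDiff = 200L, neighborWindow = 50L,
                            varianceThreshold = 0.001, kPair = 1L) {
  cfg <- list(kTop = as.integer(kTop), kDiff = as.integer(kDiff),
              neighborWindow = as.integer(neighborWindow),
              varianceThreshold = as.numeric(varianceThreshold),
              kPair = as.integer(kPair))
  if (any(unlist(cfg) <= 0)) stop("all selection parameters must be positive")
  structure(cfg, class = "SelectionConfig")
}

#' Merge two methylation atlases by probe ID
#'
#' Joins the probe rows of a base atlas (e.g. a published reference) with an
#' extension (e.g. additional tissue arrays) and concatenates their cell-type
#' columns. Probe order in the result is sorted by probe ID so merges are
#' deterministic.
#'
#' @param base,extension [MethylationAtlas-class] objects.
#' @param join `"inner"` (default; probes present in both) or `"outer"`
#'   (union of probes, missing betas set to `NA`).
#' @return A merged [MethylationAtlas-class].
#' @examples
#' a <- MethylationAtlas(matrix(c(.1, .9), 2, dimnames = list(c("cg1","cg2"), "A")))
#' b <- MethylationAtlas(matrix(c(.5, .7), 2, dimnames = list(c("cg2","cg3"), "B")))
#' mergeAtlases(a, b)                  # inner join: cg2 only
#' @export
mergeAtlases <- function(base, extension, join = c("inner", "outer")) {
  join <- match.arg(join)
  stopifnot(is(base, "MethylationAtlas"), is(extension, "MethylationAtlas"))
  dup <- intersect(cellTypes(base), cellTypes(extension))
  if (length(dup))
    stop("duplicate cell-type labels across atlases: ",
         paste(dup, collapse = ", "),
         " (suffix replicates before merging)")
  pb <- probeIDs(base); pe <- probeIDs(extension)
  probes <- if (join == "inner") sort(intersect(pb, pe)) else sort(union(pb, pe))
  if (!length(probes)) stop("no probes survive the ", join, " join")
  b <- matrix(NA_real_, length(probes),
              ncol(betaValues(base)) + ncol(betaValues(extension)),
              dimnames = list(probes, c(cellTypes(base), cellTypes(extension))))
  ib <- intersect(probes, pb); ie <- intersect(probes, pe)
  b[ib, cellTypes(base)] <- betaValues(base)[ib, , drop = FALSE]
  b[ie, cellTypes(extension)] <- betaValues(extension)[ie, , drop = FALSE]
  coords <- probeCoords(base)
  ce <- probeCoords(extension)
  if (is.null(coords)) coords <- ce
  else if (!is.null(ce)) {
    extra <- ce[!names(ce) %in% names(coords)]
    coords <- c(coords, extra)
  }
  if (!is.null(coords)) coords <- coords[names(coords) %in% probes]
  MethylationAtlas(b, coords)
}

#' Filter atlas rows and pool replicate columns per tissue
#'
#' Removes probes with any missing beta value or with row-wise population
#' variance below `varianceThreshold`, then averages replicate columns into
#' one column per tissue.
#'
#' @param atlas a [MethylationAtlas-class].
#' @param tissueMap named character vector mapping every column name to its
#'   tissue label. Default `NULL` strips a trailing `"_rep<k>"` suffix from
#'   column names.
#' @param varianceThreshold minimum row-wise population variance (default
#'   0.001).
#' @return A pooled, complete-case [MethylationAtlas-class].
#' @export
filterAndPool <- function(atlas, tissueMap = NULL, varianceThreshold = 0.001) {
  b <- betaValues(atlas)
  if (is.null(tissueMap)) {
    tissueMap <- stats::setNames(sub("_rep[0-9]+$", "", colnames(b)), colnames(b))
  }
  if (!all(colnames(b) %in% names(tissueMap)))
    stop("tissueMap must cover all atlas columns")
  nMissing <- sum(!stats::complete.cases(b))
  keep <- stats::complete.cases(b)
  b <- b[keep, , drop = FALSE]
  v <- rowPopVar(b)
  nLowVar <- sum(v < varianceThreshold)
  b <- b[v >= varianceThreshold, , drop = FALSE]
  if (!nrow(b))
    stop(sprintf(paste0("no probes left after filtering ",
                        "(%d removed for missing values, %d for variance < %g)"),
                 nMissing, nLowVar, varianceThreshold))
  tissues <- unname(tissueMap[colnames(b)])
  uniqueT <- unique(tissues)
  pooled <- matrix(NA_real_, nrow(b), length(uniqueT),
                   dimnames = list(rownames(b), uniqueT))
  for (t in uniqueT)
    pooled[, t] <- rowMeans(b[, tissues == t, drop = FALSE])
  coords <- probeCoords(atlas)
  if (!is.null(coords)) coords <- coords[names(coords) %in% rownames(pooled)]
  MethylationAtlas(pooled, coords)
}

# Rank probes of one scaled column, highest value first, ties by probe ID.
.rank_desc <- function(values, ids) order(-values, ids)

#' Select top hyper- and hypomethylated CpGs per cell type (row-scaled)
#'
#' The atlas is scaled by dividing each row by its row sum; for each cell
#' type (processed in sorted column order) the `k` probes with the highest
#' scaled value are selected, skipping probes already claimed by a previously
#' processed cell type. The procedure is repeated on the reversed matrix
#' (`1 - beta`, row-scaled) for hypomethylated probes; the exclusion list is
#' shared across both passes, so all selected sets are pairwise disjoint.
#' Rows with zero row sum are skipped in the corresponding pass.
#'
#' @param atlas pooled [MethylationAtlas-class] without missing values.
#' @param k probes per direction per cell type (default 100).
#' @return list with elements `hyper` and `hypo`, each a named list of probe
#'   ID vectors (one per cell type).
#' @export
selectTopScaled <- function(atlas, k = 100L) {
  b <- betaValues(atlas)
  if (anyNA(b)) stop("atlas must be filtered (no missing values)")
  stopifnot(k >= 1)
  cts <- sort(colnames(b))
  used <- character(0)
  out <- list(hyper = list(), hypo = list())
  for (direction in c("hyper", "hypo")) {
    m <- if (direction == "hyper") b else 1 - b
    rs <- rowSums(m)
    m <- m[rs > 0, , drop = FALSE]
    s <- m / rowSums(m)
    ids <- rownames(s)
    for (ct in cts) {
      ord <- .rank_desc(s[, ct], ids)
      eligible <- ids[ord]
      eligible <- eligible[!eligible %in% used]
      if (length(eligible) < k)
        warning(sprintf("cell type '%s' (%s): only %d eligible probes for k = %d",
                        ct, direction, length(eligible), k))
      sel <- utils::head(eligible, k)
      used <- c(used, sel)
      out[[direction]][[ct]] <- sel
    }
  }
  out
}

#' Select the most differential CpGs per cell type (one-vs-rest)
#'
#' Ranks probes by how strongly they separate one cell type from all others
#' on the unscaled atlas. With at least two replicate columns on each side
#' (per `tissueMap`) a two-group one-way ANOVA F statistic is used and probes
#' are ranked by ascending p; with pooled single columns the score is
#' `|beta_target - mean(beta_others)| / (sd(beta_others) + 1e-6)`, ranked
#' descending. Ties break by probe ID.
#'
#' @param atlas a [MethylationAtlas-class] (may contain replicate columns).
#' @param k probes per cell type (default 200).
#' @param tissueMap optional named character vector (column -> tissue). When
#'   supplied and every tissue has >= 2 replicate columns, the F-statistic
#'   path is used; otherwise columns are treated as pooled tissues.
#' @return named list of probe ID vectors, one per tissue.
#' @export
selectMostDifferential <- function(atlas, k = 200L, tissueMap = NULL) {
  b <- betaValues(atlas)
  if (anyNA(b)) stop("atlas must not contain missing values")
  if (ncol(b) < 2) stop("need >= 2 columns for one-vs-rest ranking")
  if (k > nrow(b)) {
    warning(sprintf("k = %d exceeds probe count %d; returning all probes", k, nrow(b)))
    k <- nrow(b)
  }
  ids <- rownames(b)
  useF <- FALSE
  if (!is.null(tissueMap)) {
    if (!all(colnames(b) %in% names(tissueMap)))
      stop("tissueMap must cover all atlas columns")
    tis <- unname(tissueMap[colnames(b)])
    useF <- all(table(tis) >= 2) && length(unique(tis)) >= 2
  } else {
    tis <- colnames(b)
  }
  tissues <- unique(tis)
  out <- vector("list", length(tissues))
  names(out) <- tissues
  for (t in tissues) {
    inT <- tis == t
    if (useF) {
      x1 <- b[, inT, drop = FALSE]; x2 <- b[, !inT, drop = FALSE]
      n1 <- ncol(x1); n2 <- ncol(x2); n <- n1 + n2
      m1 <- rowMeans(x1); m2 <- rowMeans(x2)
      m <- (n1 * m1 + n2 * m2) / n
      ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
      ssw <- rowSums((x1 - m1)^2) + rowSums((x2 - m2)^2)
      fstat <- ssb / (ssw / (n - 2))
      fstat[ssw == 0 & ssb > 0] <- Inf
      fstat[ssw == 0 & ssb == 0] <- 0
      p <- stats::pf(fstat, 1, n - 2, lower.tail = FALSE)
      ord <- order(p, -fstat, ids)
      score_spread <- diff(range(fstat))
    } else {
      others <- b[, !inT, drop = FALSE]
      mo <- rowMeans(others)
      so <- if (ncol(others) > 1) apply(others, 1, stats::sd) else 0
      score <- abs(rowMeans(b[, inT, drop = FALSE]) - mo) / (so + 1e-6)
      ord <- order(-score, ids)
      score_spread <- diff(range(score))
    }
    if (score_spread == 0)
      warning(sprintf("no differential signal for '%s'; returning %d probes by ID order", t, k))
    out[[t]] <- ids[ord][seq_len(k)]
  }
  out
}

#' Add neighboring CpGs within a bp window of selected probes
#'
#' @param selected character vector of probe IDs already selected.
#' @param atlas a [MethylationAtlas-class] with probe coordinates.
#' @param window maximum distance in bp (same chromosome, `|delta pos| <=
#'   window`; default 50).
#' @return character vector: union of `selected` and its neighbors. If the
#'   atlas has no coordinates the step is skipped with a warning.
#' @export
addNeighbors <- function(selected, atlas, window = 50L) {
  coords <- probeCoords(atlas)
  if (is.null(coords)) {
    warning("atlas has no coordinates; neighbor step skipped")
    return(selected)
  }
  sel <- coords[names(coords) %in% selected]
  if (!length(sel)) return(selected)
  widened <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(sel),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(sel) - window),
                     GenomicRanges::start(sel) + window)
  )
  hits <- GenomicRanges::findOverlaps(coords, widened, ignore.strand = TRUE)
  neigh <- names(coords)[unique(S4Vectors::queryHits(hits))]
  sort(union(selected, neigh))
}

#' Add pairwise-specific CpGs
#'
#' For each unordered pair of cell types, adds the `kPair` probes with the
#' largest absolute beta difference between the two types among probes not
#' yet selected. Pairs are processed in sorted order; ties break by probe ID.
#'
#' @param atlas pooled [MethylationAtlas-class].
#' @param selected character vector of probes already selected.
#' @param kPair probes per pair (default 1).
#' @return character vector: union of `selected` and the pairwise additions
#'   (attribute `"added"` lists the new probes).
#' @export
addPairwiseSpecific <- function(atlas, selected, kPair = 1L) {
  b <- betaValues(atlas)
  if (anyNA(b)) stop("atlas must be pooled and complete")
  cts <- sort(colnames(b))
  ids <- rownames(b)
  sel <- selected
  added <- character(0)
  if (length(cts) >= 2) {
    pairs <- utils::combn(cts, 2)
    for (i in seq_len(ncol(pairs))) {
      d <- abs(b[, pairs[1, i]] - b[, pairs[2, i]])
      ord <- order(-d, ids)
      cand <- ids[ord]
      cand <- cand[!cand %in% sel]
      take <- utils::head(cand, kPair)
      sel <- c(sel, take)
      added <- c(added, take)
    }
  }
  out <- sort(unique(sel))
  attr(out, "added") <- sort(unique(added))
  out
}

#' Assemble a signature matrix from selection sets
#'
#' Takes the deduplicated union of all selection sets, records per-probe
#' provenance with fixed precedence `hyper > hypo > differential > neighbor >
#' pairwise`, and returns the corresponding pooled-atlas submatrix with rows
#' sorted by probe ID.
#'
#' @param atlas pooled [MethylationAtlas-class] containing all selected
#'   probes.
#' @param selections list with any of the elements `hyper`, `hypo`,
#'   `differential` (each either a character vector or a named list per cell
#'   type), `neighbor` and `pairwise` (character vectors).
#' @return A [SignatureMatrix-class].
#' @export
buildSignature <- function(atlas, selections) {
  b <- betaValues(atlas)
  tags <- c(hyper = "hyper_topk", hypo = "hypo_topk",
            differential = "differential", neighbor = "neighbor",
            pairwise = "pairwise")
  prov <- character(0)
  perType <- list()
  for (nm in names(tags)) {
    s <- selections[[nm]]
    if (is.null(s)) next
    if (is.list(s)) {
      for (ct in names(s)) perType[[ct]] <- c(perType[[ct]], s[[ct]])
      s <- unlist(s, use.names = FALSE)
    }
    s <- unique(as.character(s))
    new <- setdiff(s, names(prov))
    prov[new] <- tags[[nm]]
  }
  probes <- sort(names(prov))
  if (!length(probes)) stop("empty selection: no probes to assemble")
  missing <- setdiff(probes, rownames(b))
  if (length(missing))
    stop("selected probes absent from atlas: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (length(perType)) {
    empty <- names(perType)[vapply(perType, length, 1L) == 0]
    orphan <- setdiff(colnames(b), names(perType))
    if (length(c(empty, orphan)))
      warning("cell types without own selected probes: ",
              paste(c(empty, orphan), collapse = ", "))
  }
  coords <- probeCoords(atlas)
  if (!is.null(coords)) coords <- coords[names(coords) %in% probes]
  new("SignatureMatrix",
      beta = b[probes, , drop = FALSE],
      coords = coords,
      provenance = unname(prov[probes]))
}

#' Build a signature matrix from a raw atlas in one call
#'
#' Runs the full selection pipeline: [filterAndPool()] (missing-value and
#' variance filtering, replicate pooling), [selectTopScaled()] on the pooled
#' atlas, [selectMostDifferential()], [addNeighbors()] and
#' [addPairwiseSpecific()], then [buildSignature()].
#'
#' @param atlas a [MethylationAtlas-class] (may contain replicates, missing
#'   values).
#' @param config a [selectionConfig()] list.
#' @param tissueMap optional column -> tissue map (see [filterAndPool()]).
#' @return A [SignatureMatrix-class].
#' @export
buildSignatureMatrix <- function(atlas, config = selectionConfig(),
                                 tissueMap = NULL) {
  if (is.null(tissueMap)) {
    cn <- colnames(betaValues(atlas))
    tissueMap <- stats::setNames(sub("_rep[0-9]+$", "", cn), cn)
  }
  pooled <- filterAndPool(atlas, tissueMap, config$varianceThreshold)
  top <- selectTopScaled(pooled, config$kTop)
  raw <- betaValues(atlas)
  keepIdx <- rownames(raw) %in% probeIDs(pooled)
  unscaled <- MethylationAtlas(raw[keepIdx, , drop = FALSE], probeCoords(pooled))
  diffSel <- selectMostDifferential(
    unscaled, k = min(config$kDiff, nrow(betaValues(pooled))),
    tissueMap = tissueMap
  )
  # differential selection may run on replicate columns; map back to tissues
  core <- unique(c(unlist(top$hyper), unlist(top$hypo), unlist(diffSel)))
  withNeigh <- addNeighbors(core, pooled, config$neighborWindow)
  neighborOnly <- setdiff(withNeigh, core)
  withPairs <- addPairwiseSpecific(pooled, withNeigh, config$kPair)
  buildSignature(pooled, list(
    hyper = top$hyper, hypo = top$hypo, differential = diffSel,
    neighbor = neighborOnly, pairwise = attr(withPairs, "added")
  ))
}

#' Read / write atlas and signature files
#'
#' `readAtlas()` reads a CSV whose first column holds CpG probe IDs and the
#' remaining columns beta values per cell type, with an optional coordinate
#' sidecar CSV (`probe_id, chrom, pos, strand`). `writeSignature()` writes a
#' signature as TSV with a provenance column; `readSignature()` reads it
#' back.
#'
#' @param path file path.
#' @param coordsPath optional coordinate sidecar CSV path.
#' @return `readAtlas()` a [MethylationAtlas-class]; `readSignature()` a
#'   [SignatureMatrix-class]; `writeSignature()` (invisibly) the path.
#' @export
readAtlas <- function(path, coordsPath = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  b <- as.matrix(df[, -1, drop = FALSE])
  rownames(b) <- as.character(df[[1]])
  coords <- NULL
  if (!is.null(coordsPath)) {
    cd <- utils::read.csv(coordsPath, stringsAsFactors = FALSE)
    coords <- .coords_to_granges(cd)
    coords <- coords[names(coords) %in% rownames(b)]
  }
  MethylationAtlas(b, coords)
}

#' @rdname readAtlas
#' @param atlas a [MethylationAtlas-class] to write as CSV.
#' @export
writeAtlas <- function(atlas, path) {
  b <- betaValues(atlas)
  df <- data.frame(IlmnID = rownames(b), b, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readAtlas
#' @param signature a [SignatureMatrix-class].
#' @export
writeSignature <- function(signature, path) {
  b <- betaValues(signature)
  df <- data.frame(IlmnID = rownames(b), b,
                   provenance = provenance(signature),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname readAtlas
#' @export
readSignature <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  prov <- df$provenance
  b <- as.matrix(df[, setdiff(names(df), c("IlmnID", "provenance")), drop = FALSE])
  rownames(b) <- df$IlmnID
  new("SignatureMatrix", beta = b, coords = NULL, provenance = prov)
}
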
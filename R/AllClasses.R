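#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom GenomicRanges GRanges seqnames start
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
NULL

setClassUnion("GRangesOrNULL", c("GRanges", "NULL"))

#' MethylationAtlas: a reference methylation atlas
#'
#' A probe-by-cell-type matrix of methylation beta values (fractions of
#' methylated reads, in \[0, 1\]) measured on purified cell and tissue types.
#' Columns may be biological replicates of the same tissue (conventionally
#' suffixed, e.g. `"Heart_rep1"`); [filterAndPool()] averages replicates into
#' one column per tissue. Probe genomic coordinates are optional and only
#' required by coordinate-aware steps ([addNeighbors()]).
#'
#' @slot beta numeric matrix, probes in rows (unique rownames = probe IDs),
#'   cell types in columns. `NA` allowed before filtering; all non-missing
#'   values must lie in \[0, 1\].
#' @slot coords `GRanges` of probe CpG positions (width-1 ranges, names =
#'   probe IDs), or `NULL` when coordinates are unknown.
#'
#' @seealso [MethylationAtlas()] constructor, [readAtlas()], [mergeAtlases()],
#'   [filterAndPool()]
#' @export
setClass("MethylationAtlas",
  representation(beta = "matrix", coords = "GRangesOrNULL"),
  prototype(beta = matrix(numeric(0), 0, 0), coords = NULL)
)

setValidity("MethylationAtlas", function(object) {
  msg <- character(0)
  b <- object@beta
  if (!is.numeric(b)) msg <- c(msg, "beta must be a numeric matrix")
  if (is.null(rownames(b)) || anyDuplicated(rownames(b)))
    msg <- c(msg, "probe IDs (rownames of beta) must be present and unique")
  if (is.null(colnames(b)) || ncol(b) < 1L)
    msg <- c(msg, "cell types (colnames of beta) must be non-empty")
  v <- b[!is.na(b)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    msg <- c(msg, "non-missing beta values must lie in [0, 1]")
  if (!is.null(object@coords)) {
    if (is.null(names(object@coords)) ||
        !all(names(object@coords) %in% rownames(b)))
      msg <- c(msg, "coords must be named by probe IDs present in the atlas")
  }
  if (length(msg)) msg else TRUE
})

#' SignatureMatrix: a cell-type-specific CpG signature
#'
#' A [MethylationAtlas-class] restricted to probes that discriminate cell
#' types, with one pooled column per tissue and a per-probe provenance tag
#' recording which selection step claimed the probe first (fixed precedence
#' `hyper > hypo > differential > neighbor > pairwise`).
#'
#' @slot provenance character vector parallel to the probe rows, values in
#'   `c("hyper_topk", "hypo_topk", "differential", "neighbor", "pairwise")`.
#'
#' @seealso [buildSignature()], [deconvolute()]
#' @export
setClass("SignatureMatrix",
  contains = "MethylationAtlas",
  representation(provenance = "character")
)

.provenance_levels <- c("hyper_topk", "hypo_topk", "differential",
                        "neighbor", "pairwise")

setValidity("SignatureMatrix", function(object) {
  msg <- character(0)
  if (anyNA(object@beta)) msg <- c(msg, "signature must not contain missing values")
  if (length(object@provenance) != nrow(object@beta))
    msg <- c(msg, "provenance must have one entry per probe")
  if (!all(object@provenance %in% .provenance_levels))
    msg <- c(msg, sprintf("provenance values must be in {%s}",
                          paste(.provenance_levels, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' MethylationCallSet: per-sample CpG methylation calls
#'
#' Stranded per-CpG methylation counts of one sample, as produced by
#' bisulfite-sequencing methylation callers. Positions are 1-based and refer
#' to the cytosine of the CpG; `strand` is `"+"` or `"-"`.
#'
#' @slot sampleID length-1 character sample identifier.
#' @slot calls data.frame with columns `chrom` (character), `pos` (integer,
#'   1-based), `strand` (`"+"`/`"-"`), `meth` (methylated read count) and
#'   `cov` (total read count), one row per (chrom, pos, strand).
#'
#' @seealso [readCalls()], [collapseStrands()], [mapToProbes()], [tileCounts()]
#' @export
setClass("MethylationCallSet",
  representation(sampleID = "character", calls = "data.frame")
)

setValidity("MethylationCallSet", function(object) {
  msg <- character(0)
  if (length(object@sampleID) != 1L || is.na(object@sampleID))
    msg <- c(msg, "sampleID must be a single non-missing string")
  cl <- object@calls
  need <- c("chrom", "pos", "strand", "meth", "cov")
  if (!all(need %in% names(cl))) {
    msg <- c(msg, sprintf("calls must have columns %s", paste(need, collapse = ", ")))
  } else if (nrow(cl)) {
    if (!all(cl$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
    if (any(cl$cov < 1)) msg <- c(msg, "coverage must be >= 1")
    if (any(cl$meth < 0 | cl$meth > cl$cov))
      msg <- c(msg, "methylated counts must satisfy 0 <= meth <= cov")
    if (anyDuplicated(cl[c("chrom", "pos", "strand")]))
      msg <- c(msg, "(chrom, pos, strand) must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MethylationAtlas
#'
#' @param beta numeric matrix of beta values, rownames = probe IDs,
#'   colnames = cell types.
#' @param coords optional `GRanges` named by probe ID, or a data.frame with
#'   columns `probe_id`, `chrom`, `pos` (1-based) and optionally `strand`.
#' @return A [MethylationAtlas-class] object.
#' @examples
#' b <- matrix(c(0.9, 0.1, 0.1, 0.9), 2,
#'             dimnames = list(c("cg01", "cg02"), c("A", "B")))
#' MethylationAtlas(b)
#' @export
MethylationAtlas <- function(beta, coords = NULL) {
  beta <- as.matrix(beta)
  storage.mode(beta) <- "double"
  if (is.data.frame(coords)) coords <- .coords_to_granges(coords)
  new("MethylationAtlas", beta = beta, coords = coords)
}

.coords_to_granges <- function(df) {
  stopifnot(all(c("probe_id", "chrom", "pos") %in% names(df)))
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = as.integer(df$pos), width = 1L),
    strand = strand
  )
  names(gr) <- as.character(df$probe_id)
  gr
}

#' Construct a MethylationCallSet
#'
#' @param sampleID sample identifier.
#' @param calls data.frame with columns `chrom`, `pos`, `strand`, `meth`,
#'   `cov`.
#' @return A [MethylationCallSet-class] object with calls sorted by
#'   (chrom, pos, strand).
#' @export
MethylationCallSet <- function(sampleID, calls) {
  calls <- as.data.frame(calls)
  calls$chrom <- as.character(calls$chrom)
  calls$pos <- as.integer(calls$pos)
  calls$strand <- as.character(calls$strand)
  calls$meth <- as.integer(round(calls$meth))
  calls$cov <- as.integer(round(calls$cov))
  calls <- calls[order(calls$chrom, calls$pos, calls$strand), , drop = FALSE]
  rownames(calls) <- NULL
  new("MethylationCallSet", sampleID = as.character(sampleID), calls = calls)
}
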
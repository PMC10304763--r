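#' Collapse CpG calls onto the plus strand
#'
#' CpG dyads are palindromic: a minus-strand cytosine call at position `p`
#' reports the same CpG as the plus-strand call at `p - 1`. This merges each
#' minus-strand record into its plus-strand partner by summing methylated and
#' total read counts. Minus-strand records with no plus-strand partner are
#' kept (re-anchored at `p - 1` on the plus strand) with a warning.
#'
#' @param calls a [MethylationCallSet-class].
#' @return A [MethylationCallSet-class] with all records on the plus strand.
#'   Total methylated and coverage counts are conserved.
#' @export
collapseStrands <- function(calls) {
  cl <- methCalls(calls)
  if (!nrow(cl)) return(calls)
  minus <- cl$strand == "-"
  if (!any(minus)) return(calls)
  plus <- cl[!minus, , drop = FALSE]
  mn <- cl[minus, , drop = FALSE]
  mn$pos <- mn$pos - 1L          # re-anchor at the dyad's plus-strand C
  mn$strand <- "+"
  key <- function(d) paste(d$chrom, d$pos)
  idx <- match(key(mn), key(plus))
  hit <- !is.na(idx)
  if (any(hit)) {
    plus$meth[idx[hit]] <- plus$meth[idx[hit]] + mn$meth[hit]
    plus$cov[idx[hit]] <- plus$cov[idx[hit]] + mn$cov[hit]
  }
  if (any(!hit)) {
    warning(sprintf("%d minus-strand records had no plus-strand dyad partner; kept at pos - 1",
                    sum(!hit)))
    plus <- rbind(plus, mn[!hit, , drop = FALSE])
  }
  MethylationCallSet(sampleID(calls), plus)
}

#' Read an array probe manifest
#'
#' Reads a manifest CSV with columns `IlmnID`, `CHR`, `MAPINFO` (1-based CpG
#' cytosine position on the plus strand) and optionally `Strand`.
#'
#' @param path manifest CSV path.
#' @return data.frame with columns `probe_id`, `chrom`, `pos`, `strand`.
#' @export
readManifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("IlmnID", "CHR", "MAPINFO")
  if (!all(need %in% names(df)))
    stop("manifest must have columns IlmnID, CHR, MAPINFO")
  out <- data.frame(probe_id = as.character(df$IlmnID),
                    chrom = as.character(df$CHR),
                    pos = as.integer(df$MAPINFO),
                    strand = if ("Strand" %in% names(df)) as.character(df$Strand) else "+",
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$probe_id)) stop("manifest probe IDs must be unique")
  out
}

#' Map methylation calls to array probe IDs
#'
#' Matches strand-collapsed CpG calls to manifest probes by exact
#' (chromosome, position) and returns a probe-indexed bulk beta profile.
#' When several call records map to one probe the beta is the
#' coverage-weighted mean (summed methylated reads over summed coverage).
#' Records below `minCoverage` are dropped first; probes without any call are
#' absent from the output.
#'
#' @param calls a strand-collapsed [MethylationCallSet-class].
#' @param manifest data.frame from [readManifest()] (columns `probe_id`,
#'   `chrom`, `pos`).
#' @param minCoverage minimum read coverage per record (default 1).
#' @return named numeric vector of betas indexed by probe ID, ready for
#'   [deconvolute()].
#' @export
mapToProbes <- function(calls, manifest, minCoverage = 1L) {
  cl <- methCalls(calls)
  if (any(cl$strand == "-"))
    stop("calls must be strand-collapsed first (see collapseStrands)")
  cl <- cl[cl$cov >= minCoverage, , drop = FALSE]
  key <- paste(cl$chrom, cl$pos)
  mkey <- paste(manifest$chrom, manifest$pos)
  idx <- match(key, mkey)
  hit <- !is.na(idx)
  if (!any(hit))
    stop("no overlap between calls and manifest positions")
  pid <- manifest$probe_id[idx[hit]]
  meth <- tapply(cl$meth[hit], pid, sum)
  cov <- tapply(cl$cov[hit], pid, sum)
  beta <- as.numeric(meth / cov)
  stats::setNames(beta, names(meth))
}
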
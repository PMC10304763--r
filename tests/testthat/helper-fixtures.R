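# Small in-code fixtures shared across tests.

# Atlas from a plain matrix, probes auto-named cg001... unless rownames set.
toyAtlas <- function(m, cellTypes = NULL, coords = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("cg%03d", seq_len(nrow(m)))
  if (!is.null(cellTypes)) colnames(m) <- cellTypes
  MethylationAtlas(m, coords)
}

# Full-rank random signature on [0,1]; seeded.
randomSignature <- function(nProbes, nTypes, seed = 1) {
  set.seed(seed)
  m <- matrix(stats::runif(nProbes * nTypes), nProbes, nTypes,
              dimnames = list(sprintf("cg%05d", seq_len(nProbes)),
                              paste0("T", seq_len(nTypes))))
  MethylationAtlas(m)
}

# A call set from vectors.
toyCalls <- function(sample, chrom, pos, meth, cov, strand = "+") {
  MethylationCallSet(sample, data.frame(
    chrom = chrom, pos = pos, strand = strand, meth = meth, cov = cov,
    stringsAsFactors = FALSE))
}

# Synthetic tiles object (the tileCounts return shape) built directly from
# count matrices -- lets tests feed dmTest without going through files.
toyTiles <- function(meth, cov, chrom = "chr1", width = 500L) {
  n <- nrow(meth)
  windows <- data.frame(chrom = chrom,
                        start = 1L + (seq_len(n) - 1L) * width,
                        stringsAsFactors = FALSE)
  windows$end <- windows$start + width
  ncpg <- matrix(3L, n, ncol(meth), dimnames = dimnames(meth))
  list(windows = windows, meth = meth, cov = cov, ncpg = ncpg)
}
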
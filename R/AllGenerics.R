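#' Accessors for atlas, signature and call-set objects
#'
#' `probeIDs()` returns probe identifiers, `cellTypes()` the tissue/cell-type
#' column labels, `betaValues()` the beta matrix, `probeCoords()` the probe
#' `GRanges` (or `NULL`), `provenance()` the per-probe selection tag of a
#' signature, `sampleID()` the sample label and `methCalls()` the call table.
#'
#' @param x a [MethylationAtlas-class], [SignatureMatrix-class] or
#'   [MethylationCallSet-class] object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("probeIDs", function(x) standardGeneric("probeIDs"))

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))

#' @rdname accessors
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))

#' @rdname accessors
#' @export
setGeneric("probeCoords", function(x) standardGeneric("probeCoords"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("sampleID", function(x) standardGeneric("sampleID"))

#' @rdname accessors
#' @export
setGeneric("methCalls", function(x) standardGeneric("methCalls"))

#' @rdname accessors
setMethod("probeIDs", "MethylationAtlas", function(x) rownames(x@beta))

#' @rdname accessors
setMethod("cellTypes", "MethylationAtlas", function(x) colnames(x@beta))

#' @rdname accessors
setMethod("betaValues", "MethylationAtlas", function(x) x@beta)

#' @rdname accessors
setMethod("probeCoords", "MethylationAtlas", function(x) x@coords)

#' @rdname accessors
setMethod("provenance", "SignatureMatrix", function(x) {
  stats::setNames(x@provenance, rownames(x@beta))
})

#' @rdname accessors
setMethod("sampleID", "MethylationCallSet", function(x) x@sampleID)

#' @rdname accessors
setMethod("methCalls", "MethylationCallSet", function(x) x@calls)

setMethod("show", "MethylationAtlas", function(object) {
  cat(sprintf("%s with %d probes x %d cell types\n",
              class(object), nrow(object@beta), ncol(object@beta)))
  cat("cell types:", paste(utils::head(colnames(object@beta), 6),
                           collapse = ", "),
      if (ncol(object@beta) > 6) "..." else "", "\n")
  cat(sprintf("missing values: %d; coordinates: %s\n",
              sum(is.na(object@beta)),
              if (is.null(object@coords)) "none" else "present"))
})

setMethod("show", "SignatureMatrix", function(object) {
  callNextMethod()
  cat("provenance:", paste(sprintf("%s=%d", names(table(object@provenance)),
                                   table(object@provenance)), collapse = " "),
      "\n")
})

setMethod("show", "MethylationCallSet", function(object) {
  cat(sprintf("MethylationCallSet '%s': %d CpG records on %d chromosome(s)\n",
              object@sampleID, nrow(object@calls),
              length(unique(object@calls$chrom))))
})

#' Subset an atlas or signature by probe and/or cell type
#'
#' @param x a [MethylationAtlas-class] or [SignatureMatrix-class].
#' @param i probe selector (IDs, indices or logical).
#' @param j cell-type selector.
#' @param ... ignored.
#' @param drop ignored (matrix structure is always kept).
#' @return An object of the same class.
#' @export
setMethod("[", "MethylationAtlas", function(x, i, j, ..., drop = FALSE) {
  b <- x@beta
  if (!missing(i)) b <- b[i, , drop = FALSE]
  if (!missing(j)) b <- b[, j, drop = FALSE]
  coords <- x@coords
  if (!is.null(coords)) coords <- coords[names(coords) %in% rownames(b)]
  initialize(x, beta = b, coords = coords)
})

#' @rdname sub-MethylationAtlas-ANY-ANY-ANY-method
#' @export
setMethod("[", "SignatureMatrix", function(x, i, j, ..., drop = FALSE) {
  prov <- stats::setNames(x@provenance, rownames(x@beta))
  b <- x@beta
  if (!missing(i)) b <- b[i, , drop = FALSE]
  if (!missing(j)) b <- b[, j, drop = FALSE]
  coords <- x@coords
  if (!is.null(coords)) coords <- coords[names(coords) %in% rownames(b)]
  initialize(x, beta = b, coords = coords,
             provenance = unname(prov[rownames(b)]))
})

#' Number of probes / cell types
#' @param x a [MethylationAtlas-class].
#' @return integer vector `c(probes, cell_types)`.
#' @export
setMethod("dim", "MethylationAtlas", function(x) dim(x@beta))
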
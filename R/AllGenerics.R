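#' @importFrom BiocGenerics counts score strand start end width
NULL

#' Accessors for tadevol S4 classes
#'
#' `chrom()`, `binSize()` and `nbins()` retrieve the chromosome name, bin
#' width and bin count; `counts()` the contact matrix; `score()` the
#' insulation score vector; `insWindows()` the diamond window sizes (bp);
#' `diamondMeans()` the retained per-window diamond means; `mapBlocks()` the
#' block table of a [CoordinateMap-class].
#'
#' @param x a `ContactMatrix`, `InsulationTrack` or `CoordinateMap`.
#' @param object a `ContactMatrix` (for `counts`).
#' @param ... ignored.
#' @return The slot contents described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chrom", function(x) standardGeneric("chrom"))
#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @rdname accessors
#' @export
setGeneric("nbins", function(x) standardGeneric("nbins"))
#' @rdname accessors
#' @export
setGeneric("insWindows", function(x) standardGeneric("insWindows"))
#' @rdname accessors
#' @export
setGeneric("diamondMeans", function(x) standardGeneric("diamondMeans"))
#' @rdname accessors
#' @export
setGeneric("mapBlocks", function(x) standardGeneric("mapBlocks"))

#' @rdname accessors
#' @export
setMethod("chrom", "ContactMatrix", function(x) x@chrom)
#' @rdname accessors
#' @export
setMethod("binSize", "ContactMatrix", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("nbins", "ContactMatrix", function(x) nrow(x@counts))
#' @rdname accessors
#' @export
setMethod("counts", "ContactMatrix", function(object, ...) object@counts)

#' @rdname accessors
#' @export
setMethod("chrom", "InsulationTrack", function(x) x@chrom)
#' @rdname accessors
#' @export
setMethod("binSize", "InsulationTrack", function(x) x@binSize)
#' @rdname accessors
#' @export
setMethod("nbins", "InsulationTrack", function(x) length(x@score))
#' @rdname accessors
#' @export
setMethod("score", "InsulationTrack", function(x, ...) x@score)
#' @rdname accessors
#' @export
setMethod("insWindows", "InsulationTrack", function(x) x@windows)
#' @rdname accessors
#' @export
setMethod("diamondMeans", "InsulationTrack", function(x) x@diamonds)

#' @rdname accessors
#' @export
setMethod("mapBlocks", "CoordinateMap", function(x) x@blocks)

setMethod("show", "ContactMatrix", function(object) {
  cat(sprintf("ContactMatrix: %s, %d bins @ %d bp (total %.3g counts)\n",
              object@chrom, nrow(object@counts), object@binSize,
              sum(object@counts)))
})

setMethod("show", "InsulationTrack", function(object) {
  ok <- sum(!is.na(object@score))
  cat(sprintf(
    "InsulationTrack: %s, %d bins @ %d bp; %d scored, %d window sizes\n",
    object@chrom, length(object@score), object@binSize, ok,
    length(object@windows)))
})

setMethod("show", "CoordinateMap", function(object) {
  b <- object@blocks
  cat(sprintf("CoordinateMap: %d blocks, %d src chrom(s), %.3g bp aligned\n",
              nrow(b), length(unique(b$src_chrom)),
              sum(b$src_end - b$src_start)))
})
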
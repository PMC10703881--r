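#' ContactMatrix: binned symmetric Hi-C counts for one chromosome
#'
#' Holds a single-resolution, symmetric, non-negative contact matrix for one
#' chromosome of one taxon. Bin `i` (0-based in file formats, 1-based in R
#' indexing) covers `[i * binSize, (i + 1) * binSize)`.
#'
#' @slot chrom chromosome name.
#' @slot binSize bin width in bp.
#' @slot counts symmetric numeric matrix of raw or expected contact counts.
#' @export
setClass("ContactMatrix",
  representation(chrom = "character", binSize = "integer", counts = "matrix"))

setValidity("ContactMatrix", function(object) {
  msg <- character()
  if (length(object@chrom) != 1L || !nzchar(object@chrom))
    msg <- c(msg, "'chrom' must be a single non-empty string")
  if (length(object@binSize) != 1L || object@binSize < 1L)
    msg <- c(msg, "'binSize' must be a single positive integer")
  cts <- object@counts
  if (nrow(cts) != ncol(cts))
    msg <- c(msg, "'counts' must be square")
  else if (!isSymmetric(unname(cts), tol = 1e-8))
    msg <- c(msg, "'counts' must be symmetric")
  if (any(cts < 0)) msg <- c(msg, "'counts' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a ContactMatrix
#'
#' @param counts symmetric non-negative numeric matrix.
#' @param chrom chromosome name.
#' @param binSize bin width in bp.
#' @return A [ContactMatrix-class] object.
#' @examples
#' cm <- ContactMatrix(matrix(1, 4, 4), chrom = "chr1", binSize = 10000L)
#' nbins(cm)
#' @export
ContactMatrix <- function(counts, chrom = "chr1", binSize = 10000L) {
  new("ContactMatrix", chrom = as.character(chrom),
      binSize = as.integer(binSize), counts = unname(as.matrix(counts)))
}

#' InsulationTrack: per-bin TAD-separation score
#'
#' The insulation (TAD-separation) score per bin is the mean, over several
#' diamond window sizes, of the per-window z-score of log1p diamond-mean
#' contacts. Lower values mean stronger insulation. Per-window diamond means
#' are retained in `diamonds` for testing and for boundary significance.
#'
#' @slot chrom chromosome name.
#' @slot binSize bin width in bp.
#' @slot score numeric vector, one value per bin; `NA` where any window
#'   exceeds the matrix edge.
#' @slot windows window sizes used, in bp.
#' @slot diamonds matrix of raw diamond means, bins x windows.
#' @export
setClass("InsulationTrack",
  representation(chrom = "character", binSize = "integer",
                 score = "numeric", windows = "integer",
                 diamonds = "matrix"))

setValidity("InsulationTrack", function(object) {
  msg <- character()
  if (nrow(object@diamonds) != length(object@score))
    msg <- c(msg, "'diamonds' must have one row per bin")
  if (ncol(object@diamonds) != length(object@windows))
    msg <- c(msg, "'diamonds' must have one column per window")
  if (length(msg)) msg else TRUE
})

#' CoordinateMap: ordered pairwise alignment blocks between two genomes
#'
#' A piecewise map between a source and a destination genome, as produced by
#' alignment chaining. Blocks are 0-based half-open, non-overlapping on the
#' source, with equal source and destination lengths; destination coordinates
#' are always forward-strand, with `strand = "-"` meaning the block aligns to
#' the reverse complement (per-base mapping is reflected within the block).
#'
#' @slot blocks data.frame with columns `src_chrom, src_start, src_end,
#'   dst_chrom, dst_start, dst_end, strand, score`.
#' @export
setClass("CoordinateMap", representation(blocks = "data.frame"))

.coordMapCols <- c("src_chrom", "src_start", "src_end",
                   "dst_chrom", "dst_start", "dst_end", "strand", "score")

setValidity("CoordinateMap", function(object) {
  b <- object@blocks
  msg <- character()
  if (!all(.coordMapCols %in% names(b)))
    return(paste("blocks must have columns:", paste(.coordMapCols, collapse = ", ")))
  if (nrow(b)) {
    if (any((b$src_end - b$src_start) != (b$dst_end - b$dst_start)))
      msg <- c(msg, "src and dst block lengths must be equal")
    if (any(b$src_start < 0) || any(b$src_start >= b$src_end))
      msg <- c(msg, "blocks must satisfy 0 <= src_start < src_end")
    if (any(b$score < 0)) msg <- c(msg, "scores must be >= 0")
    if (!all(b$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
    o <- order(b$src_chrom, b$src_start)
    bs <- b[o, ]
    same <- bs$src_chrom[-1] == bs$src_chrom[-nrow(bs)]
    if (nrow(bs) > 1 && any(same & bs$src_start[-1] < bs$src_end[-nrow(bs)]))
      msg <- c(msg, "blocks must not overlap on the source genome")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CoordinateMap
#'
#' @param blocks data.frame of alignment blocks (see
#'   [CoordinateMap-class]).
#' @return A [CoordinateMap-class] object with blocks sorted by source.
#' @examples
#' identityMap(10000)
#' @export
CoordinateMap <- function(blocks) {
  blocks <- as.data.frame(blocks)[, .coordMapCols]
  blocks <- blocks[order(blocks$src_chrom, blocks$src_start), , drop = FALSE]
  rownames(blocks) <- NULL
  new("CoordinateMap", blocks = blocks)
}

#' Identity coordinate map over one chromosome
#'
#' @param length chromosome length in bp.
#' @param chrom chromosome name (used for both genomes).
#' @return A [CoordinateMap-class] with a single forward block.
#' @export
identityMap <- function(length, chrom = "chr1") {
  CoordinateMap(data.frame(
    src_chrom = chrom, src_start = 0, src_end = length,
    dst_chrom = chrom, dst_start = 0, dst_end = length,
    strand = "+", score = length))
}
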
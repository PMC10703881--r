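#' Compute the insulation (TAD-separation) track of a contact matrix
#'
#' For each window size `w` (in bins) from `minDepth/binSize` to
#' `maxDepth/binSize` stepping `windowStep/binSize`, the diamond mean
#' `d(i, w)` is the mean count over bin pairs `(a, b)` with
#' `i - w <= a < i <= b < i + w` (0-based), i.e. the `w x w` block of
#' contacts crossing bin `i`. Per window, `z(i, w)` standardizes
#' `log1p d(i, w)` over all valid bins of the chromosome; the track score is
#' the mean of `z(i, w)` over windows. Lower scores mean stronger
#' insulation. Bins where any window exceeds the matrix edge are `NA`.
#'
#' @param mat a [ContactMatrix-class].
#' @param minDepth,maxDepth smallest and largest window size in bp
#'   (defaults 100 kb and 600 kb); must be multiples of the bin size.
#' @param windowStep window-size increment in bp (default 50 kb).
#' @return An [InsulationTrack-class].
#' @export
insulationTrack <- function(mat, minDepth = 100000, maxDepth = 600000,
                            windowStep = 50000) {
  bs <- binSize(mat)
  if (minDepth < bs || maxDepth < minDepth)
    stop("need binSize <= minDepth <= maxDepth", call. = FALSE)
  if (minDepth %% bs != 0 || maxDepth %% bs != 0 || windowStep %% bs != 0)
    stop("depths and step must be multiples of the bin size", call. = FALSE)
  winBp <- seq(minDepth, maxDepth, by = windowStep)
  wins <- winBp / bs
  nb <- nbins(mat)
  diamonds <- matrix(NA_real_, nb, length(wins))
  if (nb < 2 * max(wins)) {
    warning("matrix smaller than twice maxDepth: all-missing track")
    return(new("InsulationTrack", chrom = chrom(mat), binSize = bs,
               score = rep(NA_real_, nb), windows = as.integer(winBp),
               diamonds = diamonds))
  }
  cts <- counts(mat)
  # summed-area table with a zero top row / left column for O(1) block sums
  S <- matrix(0, nb + 1, nb + 1)
  S[-1, -1] <- apply(apply(cts, 2, cumsum), 1, cumsum) |> t()
  blockSum <- function(r1, r2, c1, c2)
    S[r2 + 1, c2 + 1] - S[r1, c2 + 1] - S[r2 + 1, c1] + S[r1, c1]
  zmat <- matrix(NA_real_, nb, length(wins))
  for (k in seq_along(wins)) {
    w <- wins[k]
    I <- seq(w + 1, nb - w + 1)  # 1-based bins with a full diamond
    dsum <- vapply(I, function(i) blockSum(i - w, i - 1, i, i + w - 1),
                   numeric(1))
    d <- dsum / (w * w)
    diamonds[I, k] <- d
    ld <- log1p(d)
    s <- sd(ld)
    zmat[I, k] <- if (is.na(s) || s == 0) 0 else (ld - mean(ld)) / s
  }
  wmax <- max(wins)
  score <- rep(NA_real_, nb)
  ok <- seq(wmax + 1, nb - wmax + 1)
  score[ok] <- rowMeans(zmat[ok, , drop = FALSE])
  new("InsulationTrack", chrom = chrom(mat), binSize = bs, score = score,
      windows = as.integer(winBp), diamonds = diamonds)
}

# Brute-force diamond mean, used only as documentation of the definition;
# the test suite re-implements it independently.
.diamondCells <- function(cts, i, w) {
  cts[seq(i - w, i - 1), seq(i, i + w - 1)]
}

#' Call TAD boundaries as significant local minima of the insulation track
#'
#' Candidates are local minima whose prominence (drop from the lower of the
#' two flanking local maxima) is at least `minDelta`. Significance is a
#' one-sided rank-sum test that contacts in the candidate's smallest-window
#' diamond are lower than contacts within the two flanking intra-domain
#' blocks, Benjamini-Hochberg corrected across candidates. Calls closer than
#' `minDepth` collapse to the lower-score one.
#'
#' @param track an [InsulationTrack-class] derived from `mat`.
#' @param mat the [ContactMatrix-class] the track was computed from.
#' @param minDelta minimum prominence of a local minimum.
#' @param qThreshold Benjamini-Hochberg FDR threshold.
#' @return A `GRanges` of single-bin boundary calls with metadata `score`
#'   (track value at the minimum), `delta` (prominence), `pvalue` and
#'   `qvalue`; sorted by position.
#' @export
callBoundaries <- function(track, mat, minDelta = 0.01, qThreshold = 0.05) {
  sc <- score(track)
  bs <- binSize(track)
  n <- length(sc)
  if (all(is.na(sc))) return(.emptyCalls())
  idx <- which(!is.na(sc))
  v <- sc[idx]
  m <- length(v)
  if (m < 3) return(.emptyCalls())
  isMin <- c(FALSE, v[2:(m - 1)] < v[1:(m - 2)] &
               v[2:(m - 1)] <= v[3:m], FALSE)
  isMax <- c(TRUE, v[2:(m - 1)] > v[1:(m - 2)] &
               v[2:(m - 1)] >= v[3:m], TRUE)
  mins <- which(isMin)
  if (!length(mins)) return(.emptyCalls())
  maxPos <- which(isMax)
  delta <- vapply(mins, function(j) {
    lm <- maxPos[maxPos < j]
    rm <- maxPos[maxPos > j]
    lv <- if (length(lm)) v[max(lm)] else max(v[seq_len(j)])
    rv <- if (length(rm)) v[min(rm)] else max(v[j:m])
    min(lv, rv) - v[j]
  }, numeric(1))
  keep <- delta >= minDelta
  mins <- mins[keep]; delta <- delta[keep]
  if (!length(mins)) return(.emptyCalls())
  bins <- idx[mins]  # 1-based bin indices
  w0 <- insWindows(track)[1] / bs
  cts <- counts(mat)
  nbm <- nrow(cts)
  diamond <- function(i) as.numeric(cts[seq(i - w0, i - 1),
                                        seq(i, i + w0 - 1)])
  pv <- vapply(bins, function(i) {
    cross <- diamond(i)
    # flanking diamonds at i -/+ w are distance-matched and, for a true
    # boundary, lie inside the neighbouring domains
    intra <- c(if (i - 2 * w0 >= 1) diamond(i - w0),
               if (i + 2 * w0 - 1 <= nbm) diamond(i + w0))
    if (!length(intra)) return(NA_real_)
    suppressWarnings(stats::wilcox.test(cross, intra, alternative = "less",
                                        exact = FALSE)$p.value)
  }, numeric(1))
  qv <- stats::p.adjust(pv, method = "BH")
  keep <- !is.na(qv) & qv <= qThreshold
  bins <- bins[keep]; delta <- delta[keep]; pv <- pv[keep]; qv <- qv[keep]
  if (!length(bins)) return(.emptyCalls())
  # collapse calls closer than minDepth, keeping the lower-score call
  o <- order(bins)
  bins <- bins[o]; delta <- delta[o]; pv <- pv[o]; qv <- qv[o]
  minSep <- insWindows(track)[1] / bs
  repeat {
    gaps <- diff(bins)
    tooClose <- which(gaps < minSep)
    if (!length(tooClose)) break
    j <- tooClose[1]
    drop <- if (sc[bins[j]] <= sc[bins[j + 1]]) j + 1 else j
    bins <- bins[-drop]; delta <- delta[-drop]
    pv <- pv[-drop]; qv <- qv[-drop]
  }
  gr <- GRanges(chrom(track),
                IRanges((bins - 1) * bs + 1, bins * bs))
  mcols(gr)$score <- sc[bins]
  mcols(gr)$delta <- delta
  mcols(gr)$pvalue <- pv
  mcols(gr)$qvalue <- qv
  gr
}

.emptyCalls <- function() {
  gr <- GRanges()
  mcols(gr)$score <- numeric()
  mcols(gr)$delta <- numeric()
  mcols(gr)$pvalue <- numeric()
  mcols(gr)$qvalue <- numeric()
  gr
}

#' Aggregate contact pileup and median insulation around anchors
#'
#' Averages observed/expected contact submatrices centered on anchor
#' midpoints, where the expected count is the per-diagonal chromosome mean,
#' and reports the median insulation score per offset bin. Anchors whose
#' window exceeds the matrix extent are dropped and counted.
#'
#' @param anchors a `GRanges` of anchor intervals, or a named list of them
#'   (one per taxon).
#' @param matrices a [ContactMatrix-class] or a named list matching
#'   `anchors`.
#' @param tracks optional [InsulationTrack-class] (or list) for the median
#'   score curve.
#' @param flank half-window in bp (default 1 Mb, i.e. a 2 Mb pileup).
#' @return list with `oe` (mean observed/expected matrix, `(2*flank/bin+1)`
#'   square), `medianScore` (per-offset median insulation, or `NULL`),
#'   `offsets` (bp), `nUsed`, `nDropped`.
#' @export
pileup <- function(anchors, matrices, tracks = NULL, flank = 1000000) {
  if (!is.list(anchors)) anchors <- list(anchors)
  if (!is.list(matrices)) matrices <- list(matrices)
  if (!is.null(tracks) && !is.list(tracks)) tracks <- list(tracks)
  stopifnot(length(anchors) == length(matrices))
  bs <- binSize(matrices[[1]])
  F <- as.integer(flank / bs)
  size <- 2L * F + 1L
  acc <- matrix(0, size, size)
  scoreRows <- NULL
  nUsed <- 0L; nDropped <- 0L
  for (t in seq_along(anchors)) {
    mat <- matrices[[t]]
    cts <- counts(mat)
    nb <- nrow(cts)
    # expected = per-diagonal mean
    dmean <- vapply(0:(nb - 1), function(d)
      mean(cts[cbind(seq_len(nb - d), seq_len(nb - d) + d)]), numeric(1))
    E <- matrix(dmean[abs(outer(seq_len(nb), seq_len(nb), "-")) + 1], nb, nb)
    OE <- ifelse(E > 0, cts / E, NA)
    mid <- floor((start(anchors[[t]]) - 1 + end(anchors[[t]])) / 2)
    bins <- floor(mid / bs) + 1L
    ok <- bins - F >= 1 & bins + F <= nb
    nDropped <- nDropped + sum(!ok)
    for (b in bins[ok]) {
      acc <- acc + OE[seq(b - F, b + F), seq(b - F, b + F)]
      nUsed <- nUsed + 1L
      if (!is.null(tracks))
        scoreRows <- rbind(scoreRows,
                           score(tracks[[t]])[seq(b - F, b + F)])
    }
  }
  if (nUsed == 0L) stop("no usable anchors within matrix extent",
                        call. = FALSE)
  list(oe = acc / nUsed,
       medianScore = if (!is.null(scoreRows))
         apply(scoreRows, 2, median, na.rm = TRUE) else NULL,
       offsets = seq(-F, F) * bs, nUsed = nUsed, nDropped = nDropped)
}
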
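#' Elongate alignment blocks into synteny blocks
#'
#' Seeds are blocks longer than `minLen` with score at least `minScore`.
#' Walking the blocks in source order, a seed absorbs neighboring blocks of
#' any size that are collinear with it: same source and destination
#' chromosome, same strand, destination order consistent with the strand,
#' and source and destination gaps at most `maxGap`. Output blocks are
#' maximal and non-overlapping on the source.
#'
#' @param map a [CoordinateMap-class] of raw alignment blocks.
#' @param minLen minimum seed length in bp (default 1 kb; seeds must be
#'   strictly longer).
#' @param minScore minimum seed alignment score (default 100000).
#' @param maxGap maximum source/destination gap absorbed during elongation
#'   (default 1 Mb).
#' @return A data.frame of synteny blocks: `src_chrom, src_start, src_end,
#'   dst_chrom, dst_start, dst_end, strand, score` (aggregate = max member
#'   score) and `members` (comma-separated row indices of `mapBlocks(map)`).
#' @export
elongateBlocks <- function(map, minLen = 1000, minScore = 100000,
                           maxGap = 1e6) {
  b <- mapBlocks(map)
  if (!nrow(b)) return(cbind(emptyBlockTable(), members = character()))
  b$.row <- seq_len(nrow(b))
  b <- b[order(b$src_chrom, b$src_start), , drop = FALSE]
  n <- nrow(b)
  # linkable[i]: block i+1 can be chained onto block i
  linkable <- if (n > 1) {
    cur <- b[-n, ]; nxt <- b[-1, ]
    sameCtx <- cur$src_chrom == nxt$src_chrom &
      cur$dst_chrom == nxt$dst_chrom & cur$strand == nxt$strand
    srcGap <- nxt$src_start - cur$src_end
    dstGap <- ifelse(cur$strand == "+", nxt$dst_start - cur$dst_end,
                     cur$dst_start - nxt$dst_end)
    sameCtx & srcGap >= 0 & srcGap <= maxGap & dstGap >= 0 & dstGap <= maxGap
  } else logical(0)
  chainId <- cumsum(c(TRUE, !linkable))
  isSeed <- (b$src_end - b$src_start) > minLen & b$score >= minScore
  out <- list()
  for (cid in unique(chainId)) {
    idx <- which(chainId == cid)
    if (!any(isSeed[idx])) next
    mem <- b[idx, ]
    out[[length(out) + 1L]] <- data.frame(
      src_chrom = mem$src_chrom[1], src_start = min(mem$src_start),
      src_end = max(mem$src_end), dst_chrom = mem$dst_chrom[1],
      dst_start = min(mem$dst_start), dst_end = max(mem$dst_end),
      strand = mem$strand[1], score = max(mem$score),
      members = paste(mem$.row, collapse = ","))
  }
  if (!length(out)) return(cbind(emptyBlockTable(), members = character()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Define breaks of synteny (BOS) flanking synteny blocks
#'
#' Emits the `flankWidth` region immediately upstream and downstream of each
#' elongated synteny block on the source genome, clipped at chromosome ends
#' (a flank falling entirely off the chromosome is not emitted).
#'
#' @param blocks synteny-block data.frame from [elongateBlocks()].
#' @param flankWidth flank width in bp (default 1 kb).
#' @param chromSizes named numeric vector of source chromosome sizes.
#' @return A `GRanges` of BOS regions with metadata `block` (block row),
#'   `side` (`"5p"`/`"3p"`) and `status` (`"kept"`).
#' @export
defineBOS <- function(blocks, flankWidth = 1000, chromSizes) {
  out <- list()
  for (r in seq_len(nrow(blocks))) {
    chr <- blocks$src_chrom[r]
    size <- chromSizes[[chr]]
    if (is.null(size)) stop("no chromosome size for ", chr, call. = FALSE)
    s5 <- max(0, blocks$src_start[r] - flankWidth)
    e5 <- blocks$src_start[r]
    if (e5 > s5)
      out[[length(out) + 1L]] <- data.frame(chr = chr, s = s5, e = e5,
                                            block = r, side = "5p")
    s3 <- blocks$src_end[r]
    e3 <- min(size, blocks$src_end[r] + flankWidth)
    if (e3 > s3)
      out[[length(out) + 1L]] <- data.frame(chr = chr, s = s3, e = e3,
                                            block = r, side = "3p")
  }
  if (!length(out)) return(GRanges())
  df <- do.call(rbind, out)
  gr <- GRanges(df$chr, IRanges(df$s + 1, df$e))
  mcols(gr)$block <- df$block
  mcols(gr)$side <- df$side
  mcols(gr)$status <- "kept"
  sort(gr)
}

#' Curate BOS regions by re-mapping hit ambiguity and repeat overlap
#'
#' A BOS is removed as `duplicated` when it has at least two re-mapping hits
#' and the second-best score is within `ratio` of the best (inclusive:
#' `second >= (1 - ratio) * top`; set `inclusive = FALSE` for a strict
#' inequality). A BOS with zero hits is removed as unmappable. Optionally,
#' BOS overlapping a repeat-mask interval by >= 1 bp are removed
#' (`repeat_overlap`), mechanizing the manual curation of segmental
#' duplications and large repeats.
#'
#' @param bos `GRanges` from [defineBOS()].
#' @param hits list of numeric score vectors, one per BOS (possibly empty).
#' @param ratio duplication ratio (default 0.10).
#' @param repeatMask optional `GRanges` of masked intervals.
#' @param inclusive treat a second hit at exactly `(1 - ratio) * top` as
#'   duplicated (default TRUE).
#' @return `bos` with updated `status`; kept regions have
#'   `status == "kept"`.
#' @export
duplicationFilter <- function(bos, hits, ratio = 0.10, repeatMask = NULL,
                              inclusive = TRUE) {
  stopifnot(length(hits) == length(bos))
  status <- rep("kept", length(bos))
  for (k in seq_along(bos)) {
    h <- sort(as.numeric(hits[[k]]), decreasing = TRUE)
    if (!length(h)) { status[k] <- "unmappable"; next }
    if (length(h) >= 2) {
      dup <- if (inclusive) h[2] >= (1 - ratio) * h[1]
             else h[2] > (1 - ratio) * h[1]
      if (dup) status[k] <- "duplicated"
    }
  }
  if (!is.null(repeatMask) && length(repeatMask)) {
    ov <- overlapsAny(bos, repeatMask)
    status[ov & status == "kept"] <- "repeat_overlap"
  }
  mcols(bos)$status <- status
  bos
}

#' GC-stratified random BOS sets
#'
#' Bins the observed BOS into `nStrata` GC quantile strata (quantiles taken
#' over all eligible windows of the sampling space) and draws each random
#' set uniformly among eligible windows of the matching stratum, with the
#' same per-stratum counts as observed.
#'
#' @param bos observed `GRanges` (only `status == "kept"` rows are used if a
#'   `status` column is present).
#' @param gc `GRanges` GC track (fixed-width windows with a `score` column
#'   in `[0, 1]`); its windows are the sampling space.
#' @param nSets number of random sets.
#' @param nStrata number of GC quantile strata (default 10).
#' @param seed integer seed.
#' @return list of `GRanges`, one random set per element; each carries the
#'   stratum assignment of its windows in `mcols()$stratum`.
#' @export
gcStratifiedSample <- function(bos, gc, nSets, nStrata = 10, seed = 1L) {
  if (!is.null(mcols(bos)$status)) bos <- bos[mcols(bos)$status == "kept"]
  gcv <- mcols(gc)$score
  br <- unique(quantile(gcv, probs = seq(0, 1, length.out = nStrata + 1)))
  stratumOf <- if (length(br) < 2) {
    function(v) rep(1L, length(v))  # constant GC: one stratum, uniform draw
  } else {
    function(v) as.integer(cut(v, breaks = br, include.lowest = TRUE))
  }
  winStratum <- stratumOf(gcv)
  # observed BOS GC = mean score of overlapping windows
  hits <- findOverlaps(bos, gc)
  bosGC <- tapply(gcv[subjectHits(hits)], queryHits(hits), mean)
  obsStrata <- stratumOf(as.numeric(bosGC))
  counts <- table(factor(obsStrata, levels = seq_len(max(1, length(br) - 1))))
  withSeed(substreamSeed(seed, "gc_stratified_sample"), {
    lapply(seq_len(nSets), function(set) {
      picks <- integer()
      for (s in which(counts > 0)) {
        eligible <- which(winStratum == s)
        if (!length(eligible))
          stop("no eligible windows in GC stratum ", s, call. = FALSE)
        picks <- c(picks, sample(eligible, counts[s], replace = TRUE))
      }
      g <- granges(gc[picks])
      mcols(g)$stratum <- winStratum[picks]
      g
    })
  })
}

#' Fisher test for BOS / TAD-boundary overlap against random sets
#'
#' Builds the 2x2 table of observed BOS overlapping a boundary by >= 1 bp
#' versus pooled random intervals doing so, and reports the two-sided
#' Fisher's exact p together with the log2 odds ratio and a Woolf 95% CI
#' (0.5 continuity correction when any cell is zero).
#'
#' @param bos observed `GRanges` (kept rows only if `status` present).
#' @param boundaries boundary `GRanges`.
#' @param randomSets list of `GRanges` (e.g. from [gcStratifiedSample()]).
#' @return A one-row data.frame: table cells, `log2_or`, `ci_lo`, `ci_hi`,
#'   `p`.
#' @export
bosBoundaryOverlapTest <- function(bos, boundaries, randomSets) {
  if (!length(randomSets)) stop("need >= 1 random set", call. = FALSE)
  if (!is.null(mcols(bos)$status)) bos <- bos[mcols(bos)$status == "kept"]
  obsHit <- sum(overlapsAny(bos, boundaries))
  obsMiss <- length(bos) - obsHit
  rnd <- unlist(lapply(randomSets, function(g)
    overlapsAny(g, boundaries)))
  rndHit <- sum(rnd); rndMiss <- length(rnd) - rndHit
  tab <- matrix(c(obsHit, obsMiss, rndHit, rndMiss), 2, byrow = TRUE)
  p <- stats::fisher.test(tab)$p.value
  or <- log2OddsRatio(obsHit, obsMiss, rndHit, rndMiss)
  data.frame(obs_overlap = obsHit, obs_no_overlap = obsMiss,
             rand_overlap = rndHit, rand_no_overlap = rndMiss,
             log2_or = or$log2_or, ci_lo = or$ci_lo, ci_hi = or$ci_hi,
             p = p)
}

#' Permutation test of conservation-category composition at BOS
#'
#' Compares the conservation-label composition of boundaries overlapping
#' BOS to random draws of the same number of boundaries from all labeled
#' boundaries (without replacement). For each category,
#' `p_over = #(permutation count >= observed) / nPerm` and
#' `p_under = #(<= observed) / nPerm` (plain proportions, matching the
#' 100-permutation empirical p convention; `addOne = TRUE` switches to the
#' `(k + 1) / (n + 1)` variant). Ties count on both sides, so
#' `p_over + p_under >= 1`.
#'
#' @param observedLabels character vector of labels of the boundaries
#'   overlapping BOS.
#' @param poolLabels labels of all boundaries in the genome.
#' @param nPerm number of permutations (default 100).
#' @param seed integer seed.
#' @param addOne use the `(k + 1) / (n + 1)` estimator.
#' @return data.frame per category: `observed`, `expected` (mean permuted
#'   count), `p_over`, `p_under`, plus the permutation count matrix as
#'   `attr(, "perm")`. A `p_over` of 0 is reported with the resolution note
#'   `"p < 1/nPerm"` in the `note` column.
#' @export
bosConservationPermutation <- function(observedLabels, poolLabels,
                                       nPerm = 100, seed = 1L,
                                       addOne = FALSE) {
  nObs <- length(observedLabels)
  if (!nObs) stop("observed set is empty", call. = FALSE)
  if (nObs > length(poolLabels))
    stop("observed set larger than the pool", call. = FALSE)
  cats <- sort(unique(c(observedLabels, poolLabels)))
  obsCount <- table(factor(observedLabels, levels = cats))
  perm <- withSeed(substreamSeed(seed, "bos_permutation"), {
    t(vapply(seq_len(nPerm), function(k)
      as.numeric(table(factor(sample(poolLabels, nObs), levels = cats))),
      numeric(length(cats))))
  })
  colnames(perm) <- cats
  est <- function(k, n) if (addOne) (k + 1) / (n + 1) else k / n
  res <- data.frame(
    category = cats,
    observed = as.numeric(obsCount),
    expected = colMeans(perm),
    p_over = vapply(cats, function(cc)
      est(sum(perm[, cc] >= obsCount[[cc]]), nPerm), numeric(1)),
    p_under = vapply(cats, function(cc)
      est(sum(perm[, cc] <= obsCount[[cc]]), nPerm), numeric(1)))
  res$note <- ifelse(res$p_over == 0 | res$p_under == 0,
                     sprintf("p < 1/%d", nPerm), "")
  rownames(res) <- NULL
  attr(res, "perm") <- perm
  res
}
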
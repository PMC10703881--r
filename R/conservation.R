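#' Lift intervals between genomes through a CoordinateMap
#'
#' Reproduces liftOver-style semantics: an interval lifts if and only if at
#' least `minMatch` of its bases map within a single destination
#' chromosome/strand run of consecutive map blocks; the lifted interval is
#' the span of its mapped bases in that run. Failures are reported, never
#' silently dropped.
#'
#' @param intervals a `GRanges`.
#' @param map a [CoordinateMap-class] (source = the intervals' genome).
#' @param minMatch minimum mapped fraction (default 0.95, the conventional
#'   liftOver threshold).
#' @return list with `lifted` (a `GRanges` on the destination genome
#'   carrying the metadata of the lifted rows plus `srcIndex`) and
#'   `failed` (integer indices of intervals that did not lift).
#' @export
liftIntervals <- function(intervals, map, minMatch = 0.95) {
  b <- mapBlocks(map)
  if (!nrow(b)) {
    return(list(lifted = GRanges(), failed = seq_along(intervals)))
  }
  runBreak <- c(TRUE, b$src_chrom[-1] != b$src_chrom[-nrow(b)] |
                  b$dst_chrom[-1] != b$dst_chrom[-nrow(b)] |
                  b$strand[-1] != b$strand[-nrow(b)])
  runId <- cumsum(runBreak)
  srcGr <- GRanges(b$src_chrom, IRanges(b$src_start + 1, b$src_end))
  hits <- findOverlaps(intervals, srcGr)
  liftedRows <- list()
  failed <- integer()
  for (q in seq_along(intervals)) {
    blks <- subjectHits(hits)[queryHits(hits) == q]
    s <- start(intervals[q]) - 1
    e <- end(intervals[q])
    if (!length(blks)) { failed <- c(failed, q); next }
    ovS <- pmax(s, b$src_start[blks])
    ovE <- pmin(e, b$src_end[blks])
    len <- ovE - ovS
    plus <- b$strand[blks] == "+"
    dS <- ifelse(plus, b$dst_start[blks] + (ovS - b$src_start[blks]),
                 b$dst_end[blks] - (ovE - b$src_start[blks]))
    dE <- dS + len
    runs <- runId[blks]
    perRun <- tapply(len, runs, sum)
    best <- names(perRun)[which.max(perRun)]
    if (perRun[[best]] < minMatch * (e - s)) { failed <- c(failed, q); next }
    sel <- runs == as.integer(best)
    k <- blks[sel][1]
    liftedRows[[length(liftedRows) + 1L]] <- data.frame(
      chrom = b$dst_chrom[k], start = min(dS[sel]), end = max(dE[sel]),
      strand = b$strand[k], srcIndex = q)
  }
  if (!length(liftedRows))
    return(list(lifted = GRanges(), failed = failed))
  df <- do.call(rbind, liftedRows)
  gr <- GRanges(df$chrom, IRanges(df$start + 1, df$end), strand = df$strand)
  mcols(gr) <- cbind(mcols(intervals)[df$srcIndex, , drop = FALSE],
                     DataFrame(srcIndex = df$srcIndex))
  list(lifted = gr, failed = failed)
}

#' Build a union-boundary table from per-species boundary sets
#'
#' Pools boundaries already lifted to reference coordinates and merges them
#' by single-linkage chaining: two boundaries join one union boundary when
#' the end-to-start gap between them is at most `mergeDistance` (bedtools
#' merge semantics; chains can therefore span more than `mergeDistance`
#' end-to-end). Each source boundary joins exactly one chain.
#'
#' @param boundarySets named list of `GRanges`, one per species, on the
#'   reference genome.
#' @param mergeDistance maximum gap in bp (default 10 kb).
#' @return A `GRanges` of union boundaries with logical presence columns
#'   `present.<species>` and an `n_way` count.
#' @export
buildUnion <- function(boundarySets, mergeDistance = 10000) {
  stopifnot(is.list(boundarySets), !is.null(names(boundarySets)))
  species <- names(boundarySets)
  pool <- GRanges()
  from <- integer()
  for (sp in species) {
    g <- granges(boundarySets[[sp]])
    GenomicRanges::strand(g) <- "*"
    pool <- c(pool, g)
    from <- c(from, rep(match(sp, species), length(g)))
  }
  if (!length(pool)) return(GRanges())
  un <- reduce(pool, min.gapwidth = mergeDistance + 1, with.revmap = TRUE)
  pres <- matrix(FALSE, length(un), length(species),
                 dimnames = list(NULL, species))
  rv <- mcols(un)$revmap
  for (r in seq_along(un)) pres[r, unique(from[rv[[r]]])] <- TRUE
  mcols(un)$revmap <- NULL
  for (sp in species) mcols(un)[[paste0("present.", sp)]] <- pres[, sp]
  mcols(un)$n_way <- rowSums(pres)
  un
}

.presenceMatrix <- function(union) {
  cols <- grep("^present\\.", colnames(mcols(union)), value = TRUE)
  m <- as.matrix(as.data.frame(mcols(union)[cols]))
  colnames(m) <- sub("^present\\.", "", cols)
  m
}

#' Classify union boundaries by evolutionary conservation
#'
#' Labels each union boundary from its presence flags: `ultraconserved`
#' (present in all species), `<clade>_conserved` (present in every member of
#' one clade and absent from the other; with
#' `strictOrderConservation = FALSE`, present in at least two members of the
#' clade instead of all), `<reference>_specific` (present only in a clade's
#' reference species and not within `mergeDistance` of any exclusion-set
#' interval, mirroring the outgroup filter applied to human-specific
#' boundaries), otherwise `other`.
#'
#' @param union a union-boundary `GRanges` from [buildUnion()].
#' @param clades named list of species vectors.
#' @param refs character vector of reference species (one per clade).
#' @param exclusionSets list of `GRanges` on reference coordinates
#'   (e.g. outgroup boundary sets); a reference-specific boundary within
#'   `mergeDistance` of any of them is demoted to `other`.
#' @param mergeDistance distance used for the exclusion filter (bp).
#' @param strictOrderConservation require all clade members for
#'   `<clade>_conserved` (default) rather than at least two.
#' @return `union` with a `label` metadata column added; the n-way histogram
#'   is attached as `attr(, "nWayTable")`.
#' @export
classifyConservation <- function(union, clades, refs,
                                 exclusionSets = list(),
                                 mergeDistance = 10000,
                                 strictOrderConservation = TRUE) {
  pres <- .presenceMatrix(union)
  species <- colnames(pres)
  unknown <- setdiff(species, unlist(clades))
  if (length(unknown))
    stop("species not in any clade: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  labels <- character(nrow(pres))
  for (r in seq_len(nrow(pres))) {
    p <- pres[r, ]
    labels[r] <- "other"
    if (all(p)) { labels[r] <- "ultraconserved"; next }
    done <- FALSE
    for (cl in names(clades)) {
      inCl <- p[clades[[cl]]]
      outCl <- p[setdiff(species, clades[[cl]])]
      hit <- if (strictOrderConservation) all(inCl) else sum(inCl) >= 2
      if (hit && !any(outCl)) {
        labels[r] <- paste0(cl, "_conserved"); done <- TRUE; break
      }
    }
    if (done) next
    if (sum(p) == 1 && names(p)[p] %in% refs)
      labels[r] <- paste0(names(p)[p], "_specific")
  }
  # outgroup exclusion filter for reference-specific boundaries
  if (length(exclusionSets)) {
    ss <- grep("_specific$", labels)
    if (length(ss)) {
      near <- rep(FALSE, length(ss))
      ext <- union[ss]
      for (ex in exclusionSets) {
        g <- granges(ex)
        near <- near | overlapsAny(ext + mergeDistance, g)
      }
      labels[ss[near]] <- "other"
    }
  }
  mcols(union)$label <- labels
  attr(union, "nWayTable") <- table(factor(mcols(union)$n_way,
                                           levels = seq_along(species)))
  union
}

#' Summarize boundary groups in a reference genome
#'
#' For each conservation label among boundaries present in the reference
#' species: count, fraction of reference boundaries, median insulation
#' score, fraction overlapping at least one gene, fraction with at least
#' one CTCF site and mean CTCF sites per boundary; plus two-sided Wilcoxon
#' rank-sum comparisons of insulation scores between every labeled pair and
#' each label against all reference boundaries.
#'
#' @param union a labeled union table (see [classifyConservation()]) with a
#'   numeric `score` metadata column (reference-genome insulation score per
#'   boundary).
#' @param genes,ctcf annotation `GRanges` on the reference genome.
#' @param referenceSpecies which species' boundaries to summarize; rows not
#'   present in it are ignored.
#' @return list with `summary` (per-label data.frame) and `wilcoxon`
#'   (pairwise W and p; `NA` for groups with fewer than 2 members).
#' @export
groupSummary <- function(union, genes, ctcf, referenceSpecies) {
  presCol <- paste0("present.", referenceSpecies)
  if (!presCol %in% colnames(mcols(union)))
    stop("unknown reference species: ", referenceSpecies, call. = FALSE)
  ref <- union[mcols(union)[[presCol]]]
  labels <- mcols(ref)$label
  sc <- mcols(ref)$score
  geneOv <- overlapsAny(ref, genes)
  nCtcf <- countOverlaps(ref, ctcf)
  labs <- sort(unique(labels))
  summ <- do.call(rbind, lapply(labs, function(l) {
    i <- labels == l
    data.frame(label = l, n = sum(i),
               fraction = sum(i) / length(ref),
               median_score = if (sum(i)) median(sc[i], na.rm = TRUE) else NA,
               gene_overlap_frac = mean(geneOv[i]),
               ctcf_frac = mean(nCtcf[i] >= 1),
               ctcf_per_boundary = mean(nCtcf[i]))
  }))
  pairs <- c(utils::combn(labs, 2, simplify = FALSE),
             lapply(labs, function(l) c(l, "all")))
  wil <- do.call(rbind, lapply(pairs, function(pr) {
    x <- sc[labels == pr[1]]
    y <- if (pr[2] == "all") sc else sc[labels == pr[2]]
    if (sum(!is.na(x)) < 2 || sum(!is.na(y)) < 2)
      return(data.frame(group1 = pr[1], group2 = pr[2],
                        W = NA_real_, p = NA_real_))
    wt <- suppressWarnings(stats::wilcox.test(x, y))
    data.frame(group1 = pr[1], group2 = pr[2],
               W = unname(wt$statistic), p = wt$p.value)
  }))
  list(summary = summ, wilcoxon = wil)
}

#' Gene-overlap-matched insulation permutation test
#'
#' Tests whether a boundary group's median insulation score is more extreme
#' (lower) than that of random boundary sets of the same size and the same
#' count of gene-overlapping members, drawn from all reference boundaries.
#' The empirical p-value is `(1 + #permutations with statistic <= observed)
#' / (nPerm + 1)`.
#'
#' @param union labeled union table with a `score` column (see
#'   [groupSummary()]).
#' @param groupLabel label of the group to test.
#' @param genes gene annotation `GRanges`.
#' @param referenceSpecies reference species whose boundaries form the pool.
#' @param nPerm number of permutations (must be >= 1).
#' @param seed integer seed.
#' @return list with `observed` (group median score), `p`, `nPerm` and the
#'   permutation distribution `perm`.
#' @export
matchedInsulationPermutation <- function(union, groupLabel, genes,
                                         referenceSpecies, nPerm = 1000,
                                         seed = 1L) {
  if (nPerm < 1) stop("nPerm must be >= 1", call. = FALSE)
  presCol <- paste0("present.", referenceSpecies)
  ref <- union[mcols(union)[[presCol]]]
  labels <- mcols(ref)$label
  sc <- mcols(ref)$score
  geneOv <- overlapsAny(ref, genes)
  grp <- which(labels == groupLabel)
  if (!length(grp)) stop("empty group: ", groupLabel, call. = FALSE)
  nG <- sum(geneOv[grp])
  nN <- length(grp) - nG
  poolG <- which(geneOv)
  poolN <- which(!geneOv)
  if (length(poolG) < nG || length(poolN) < nN)
    stop("cannot match gene-overlap composition from the pool",
         call. = FALSE)
  obs <- median(sc[grp], na.rm = TRUE)
  perm <- withSeed(substreamSeed(seed, "matched_permutation"), {
    vapply(seq_len(nPerm), function(k) {
      pick <- c(if (nG) sample(poolG, nG),
                if (nN) sample(poolN, nN))
      median(sc[pick], na.rm = TRUE)
    }, numeric(1))
  })
  list(observed = obs, p = (1 + sum(perm <= obs)) / (nPerm + 1),
       nPerm = nPerm, perm = perm)
}
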
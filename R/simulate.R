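#' @importFrom ape read.tree is.rooted is.binary Ntip
NULL

#' Eight-taxon phylogeny specification
#'
#' A `PhylogenySpec` bundles a rooted binary timetree with clade membership
#' and one reference taxon per clade. The default mirrors a two-clade design
#' with four primates and four rodents:
#' `(((human,(nomascus,hylobates)),rhesus),((mouse,(caroli,pahari)),rat))`
#' on an ultrametric 80-My-deep tree (gibbon genera split ~5 My ago, the
#' Mus radiation ~3 My ago).
#'
#' @param tree an `ape::phylo`, rooted and binary, branch lengths > 0.
#' @param clades named list of character vectors partitioning the tip
#'   labels (e.g. `list(primate = ..., rodent = ...)`).
#' @param refs named character vector, one reference taxon per clade.
#' @return A list of class `PhylogenySpec`.
#' @examples
#' spec <- defaultPhylogeny()
#' spec$clades$primate
#' @export
phylogenySpec <- function(tree, clades, refs) {
  if (!inherits(tree, "phylo")) stop("'tree' must be an ape phylo")
  if (!is.rooted(tree) || !is.binary(tree))
    stop("'tree' must be rooted and binary")
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stop("branch lengths must be positive")
  taxa <- tree$tip.label
  member <- unlist(clades, use.names = FALSE)
  if (length(member) != length(taxa) || !setequal(member, taxa) ||
      anyDuplicated(member))
    stop("clades must partition the tip labels")
  if (!all(names(refs) %in% names(clades)) ||
      !all(mapply(function(cl, r) r %in% clades[[cl]], names(refs), refs)))
    stop("each reference taxon must belong to its clade")
  structure(list(tree = tree, taxa = taxa, clades = clades,
                 refs = unname(refs), cladeOf = local({
                   v <- rep(names(clades), lengths(clades))
                   names(v) <- member
                   v
                 })),
            class = "PhylogenySpec")
}

#' @rdname phylogenySpec
#' @export
defaultPhylogeny <- function() {
  nwk <- system.file("extdata", "phylogeny_8taxa.nwk", package = "tadevol")
  tree <- read.tree(nwk)
  phylogenySpec(tree,
                clades = list(primate = c("human", "nomascus", "hylobates",
                                          "rhesus"),
                              rodent = c("mouse", "caroli", "pahari", "rat")),
                refs = c(primate = "human", rodent = "mouse"))
}

#' Parameters for boundary evolution on a phylogeny
#'
#' @param nBoundariesRoot number of boundaries at the root.
#' @param gainRate gain events per bp of genome per unit time (My).
#' @param lossRate per-boundary loss rate per unit time (My).
#' @param genomeLength genome length in bp.
#' @param boundaryWidth boundary interval width in bp.
#' @param minSeparation minimum distance between boundary start positions on
#'   one genome in bp. The default (150 kb) reflects typical mammalian TAD
#'   sizes, so that simulated boundaries are resolvable at the insulation
#'   window scale; positions violating it are redrawn.
#' @return A list of class `EvolutionParams`.
#' @details Default turnover rates are set so that on the default 80-My tree
#'   roughly 15% of reference-species boundaries are ultraconserved and
#'   roughly 15% are reference-specific, matching the broad structure of
#'   mammalian boundary-conservation surveys; the default genome length
#'   gives a mean boundary spacing of a few hundred kb, the observed scale
#'   of mammalian TADs.
#' @export
evolutionParams <- function(nBoundariesRoot = 55, gainRate = 8e-9,
                            lossRate = 0.01, genomeLength = 3e7,
                            boundaryWidth = 10000,
                            minSeparation = 150000) {
  stopifnot(gainRate >= 0, lossRate >= 0,
            genomeLength >= 10 * boundaryWidth, nBoundariesRoot >= 0,
            minSeparation >= boundaryWidth)
  structure(list(nBoundariesRoot = nBoundariesRoot, gainRate = gainRate,
                 lossRate = lossRate, genomeLength = genomeLength,
                 boundaryWidth = boundaryWidth,
                 minSeparation = minSeparation),
            class = "EvolutionParams")
}

# Draw n non-overlapping boundary start positions uniformly, avoiding
# intervals in `occupied` (numeric start positions). Errors after 1000
# rejection rounds: genome too small for the requested density.
.drawPositions <- function(n, occupied, genomeLength, width) {
  if (n == 0) return(numeric())
  pos <- numeric()
  for (k in seq_len(n)) {
    taken <- sort(c(occupied, pos))
    # free space for a new start: [0, L - width] minus (p - width, p + width)
    lo <- 0; hi <- genomeLength - width
    if (length(taken)) {
      cuts <- cbind(pmax(lo, taken - width + 1), pmin(hi, taken + width - 1))
      cuts <- cuts[cuts[, 1] <= cuts[, 2], , drop = FALSE]
      segs <- if (nrow(cuts)) {
        o <- order(cuts[, 1])
        cuts <- cuts[o, , drop = FALSE]
        free <- list(); cur <- lo
        for (r in seq_len(nrow(cuts))) {
          if (cuts[r, 1] > cur) free[[length(free) + 1]] <- c(cur, cuts[r, 1] - 1)
          cur <- max(cur, cuts[r, 2] + 1)
        }
        if (cur <= hi) free[[length(free) + 1]] <- c(cur, hi)
        free
      } else list(c(lo, hi))
    } else segs <- list(c(lo, hi))
    lens <- vapply(segs, function(s) s[2] - s[1] + 1, numeric(1))
    if (!length(lens) || sum(lens) <= 0)
      stop("could not place non-overlapping boundaries: genome too small",
           call. = FALSE)
    u <- runif(1, 0, sum(lens))
    seg <- segs[[findInterval(u, cumsum(lens), left.open = TRUE) + 1]]
    off <- floor(u - c(0, cumsum(lens))[findInterval(u, cumsum(lens),
                                                     left.open = TRUE) + 1])
    pos <- c(pos, min(seg[1] + off, seg[2]))
  }
  sort(pos)
}

#' Simulate boundary gain and loss along a phylogeny
#'
#' Boundaries present at the root are lost along each branch with
#' exponential rate `lossRate` (survival over a branch of length t is
#' `exp(-lossRate * t)`); new boundaries arise as a Poisson process with
#' rate `gainRate * genomeLength` per unit time, at uniform non-overlapping
#' positions, and are then themselves subject to loss. Ancestral boundaries
#' keep a lineage identifier across taxa, so true n-way conservation is
#' known exactly. Per-boundary planted insulation strength is assigned from
#' true conservation: `s = 0.1 + 0.4 * (nTaxa - nWay) / (nTaxa - 1)`, i.e.
#' boundaries shared by all taxa insulate strongly (s = 0.1) and
#' single-taxon boundaries weakly (s = 0.5).
#'
#' @param phylo a [phylogenySpec()].
#' @param params an [evolutionParams()].
#' @param seed integer master seed.
#' @return list with elements:
#'   \describe{
#'     \item{boundaries}{named list (one `GRanges` per taxon) with metadata
#'       `id` (lineage identifier) and `strength`.}
#'     \item{truth}{data.frame keyed by lineage `id`: `pos`, `presence.<taxon>`
#'       flags, `n_way`, true `label`, planted `strength`.}
#'   }
#' @export
simulateBoundaryEvolution <- function(phylo, params, seed = 1L) {
  stopifnot(inherits(phylo, "PhylogenySpec"),
            inherits(params, "EvolutionParams"))
  tree <- phylo$tree
  withSeed(substreamSeed(seed, "boundary_evolution"), {
    W <- params$boundaryWidth
    L <- params$genomeLength
    sep <- max(W, params$minSeparation)
    rootPos <- .drawPositions(params$nBoundariesRoot, numeric(), L, sep)
    nextId <- params$nBoundariesRoot + 1L
    registry <- data.frame(id = seq_len(params$nBoundariesRoot),
                           pos = rootPos)
    rootNode <- Ntip(tree) + 1L
    # states[[node]] = integer vector of lineage ids present at that node
    states <- vector("list", max(tree$edge))
    states[[rootNode]] <- registry$id
    # preorder traversal of edges
    edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
    ord <- ape::reorder.phylo(tree, "cladewise")$edge
    elen <- tree$edge.length[match(paste(ord[, 1], ord[, 2]),
                                   paste(tree$edge[, 1], tree$edge[, 2]))]
    for (e in seq_len(nrow(ord))) {
      par <- ord[e, 1]; child <- ord[e, 2]; t <- elen[e]
      present <- states[[par]]
      # losses
      if (length(present) && params$lossRate > 0) {
        keep <- runif(length(present)) < exp(-params$lossRate * t)
        present <- present[keep]
      }
      # gains (uniform over the branch; gained boundaries can be lost on the
      # same branch with the remaining time)
      nGain <- rpois(1, params$gainRate * L * t)
      if (nGain > 0) {
        tponts <- runif(nGain, 0, t)
        surv <- runif(nGain) < exp(-params$lossRate * (t - tponts))
        nGain <- sum(surv)
      }
      if (nGain > 0) {
        # avoid every registered lineage position, not just those present on
        # this branch: distinct lineages must stay resolvable after merging
        newPos <- .drawPositions(nGain, registry$pos, L, sep)
        # avoid re-using a position already registered to another lineage
        newPos <- newPos[!newPos %in% registry$pos]
        if (length(newPos)) {
          ids <- seq(nextId, length.out = length(newPos))
          nextId <- nextId + length(newPos)
          registry <- rbind(registry, data.frame(id = ids, pos = newPos))
          present <- c(present, ids)
        }
      }
      states[[child]] <- present
    }
    taxa <- tree$tip.label
    presence <- vapply(seq_along(taxa), function(i)
      registry$id %in% states[[i]], logical(nrow(registry)))
    presence <- matrix(presence, nrow = nrow(registry),
                       dimnames = list(NULL, taxa))
    keepRow <- rowSums(presence) > 0
    registry <- registry[keepRow, , drop = FALSE]
    presence <- presence[keepRow, , drop = FALSE]
    nWay <- rowSums(presence)
    labels <- labelFromPresence(presence, phylo$clades, phylo$refs)
    strength <- 0.1 + 0.4 * (length(taxa) - nWay) / (length(taxa) - 1)
    truth <- data.frame(id = registry$id, pos = registry$pos,
                        n_way = nWay, label = labels, strength = strength)
    truth <- cbind(truth, as.data.frame(presence) |>
                     stats::setNames(paste0("presence.", taxa)))
    rownames(truth) <- NULL
    boundaries <- lapply(taxa, function(tx) {
      sel <- presence[, tx]
      gr <- GRanges(rep("chr1", sum(sel)),
                    IRanges(registry$pos[sel] + 1, registry$pos[sel] + W))
      mcols(gr)$id <- registry$id[sel]
      mcols(gr)$strength <- strength[sel]
      sort(gr)
    })
    names(boundaries) <- taxa
    list(boundaries = boundaries, truth = truth)
  })
}

#' True conservation label from a presence matrix
#'
#' Applies the evolutionary grouping rules directly to presence/absence
#' flags: present in all taxa is `ultraconserved`; present in all members of
#' one clade and absent from the other is `<clade>_conserved`; present only
#' in a clade's reference taxon is `<reference>_specific`; everything else
#' is `other`.
#'
#' @param presence logical matrix, rows = boundaries, columns = taxa.
#' @param clades named list of taxon vectors.
#' @param refs character vector of reference taxa (one per clade).
#' @return character vector of labels.
#' @export
labelFromPresence <- function(presence, clades, refs) {
  presence <- as.matrix(presence)
  apply(presence, 1, function(p) {
    if (all(p)) return("ultraconserved")
    for (cl in names(clades)) {
      inCl <- p[clades[[cl]]]
      outCl <- p[setdiff(colnames(presence), clades[[cl]])]
      if (all(inCl) && !any(outCl)) return(paste0(cl, "_conserved"))
    }
    if (sum(p) == 1 && names(p)[p] %in% refs)
      return(paste0(names(p)[p], "_specific"))
    "other"
  })
}

#' Simulate a Hi-C contact matrix with planted boundary insulation
#'
#' Expected counts follow a power-law distance decay
#' `A * (j - i)^(-alpha)`, attenuated by the product of strengths `s` of all
#' boundaries strictly between bins `i` and `j` (a pair is attenuated by a
#' boundary in bin `b` when `i < b <= j`, 0-based). The diagonal is set to
#' `A`. With `noise = "poisson"` each upper-triangle cell is Poisson-sampled
#' around its expectation and mirrored.
#'
#' @param boundaries `GRanges` of boundary intervals with a `strength`
#'   metadata column (cross-boundary attenuation multiplier in (0, 1]), or
#'   `NULL` for none.
#' @param chromLength chromosome length in bp (must be a multiple of
#'   `binSize`).
#' @param binSize bin width in bp.
#' @param decayExponent power-law decay exponent alpha > 0.
#' @param baseCount expected count A at distance 1.
#' @param noise `"poisson"` or `"none"`.
#' @param seed integer seed (used only for `"poisson"`).
#' @param chrom chromosome name.
#' @return A [ContactMatrix-class].
#' @export
simulateContactMatrix <- function(boundaries, chromLength, binSize = 10000,
                                  decayExponent = 1, baseCount = 100,
                                  noise = c("poisson", "none"), seed = 1L,
                                  chrom = "chr1") {
  noise <- match.arg(noise)
  assertScalarNumber(decayExponent, "decayExponent", lower = 1e-12)
  if (chromLength %% binSize != 0)
    stop("binSize must divide chromLength", call. = FALSE)
  nb <- as.integer(chromLength / binSize)
  logAtt <- numeric(nb)  # log strength of boundary in each bin (0-based+1)
  if (!is.null(boundaries) && length(boundaries)) {
    s <- mcols(boundaries)$strength
    if (is.null(s)) stop("boundaries need a 'strength' column", call. = FALSE)
    if (any(s <= 0 | s > 1)) stop("strengths must be in (0, 1]", call. = FALSE)
    mid <- floor((start(boundaries) - 1 + end(boundaries)) / 2)
    b <- pmin(floor(mid / binSize), nb - 1) + 1L
    for (k in seq_along(b)) logAtt[b[k]] <- logAtt[b[k]] + log(s[k])
  }
  cum <- cumsum(logAtt)
  idx <- seq_len(nb)
  D <- abs(outer(idx, idx, "-"))
  M <- baseCount * ifelse(D == 0, 1, D^(-decayExponent))
  # cum is monotone non-increasing (log s <= 0), so |cum[j] - cum[i]| is the
  # summed -log s of boundaries in bins (i, j] and exp(-|.|) their product.
  M <- M * exp(-abs(outer(cum, cum, "-")))
  diag(M) <- baseCount
  if (noise == "poisson") {
    withSeed(substreamSeed(seed, "contact_matrix"), {
      up <- upper.tri(M)
      M[up] <- rpois(sum(up), M[up])
    })
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
  }
  ContactMatrix(M, chrom = chrom, binSize = as.integer(binSize))
}

#' Simulate a rearranged genome and its coordinate map
#'
#' Starts from a collinear genome of `mapLength` bp and applies `nEvents`
#' rearrangements (inversions flip a segment's strand and order;
#' translocations excise a segment and reinsert it elsewhere). The result is
#' a bijective piecewise map between the source and derived genome. True
#' breakpoints are the junctions between non-collinear blocks in the derived
#' genome (chromosome ends excluded).
#'
#' @param mapLength genome length in bp.
#' @param nEvents number of rearrangement events.
#' @param eventMix named probabilities for `inversion` and `translocation`.
#' @param minBlock minimum derived-segment length in bp.
#' @param seed integer seed.
#' @param chrom chromosome name (both genomes).
#' @return list with `map` (a [CoordinateMap-class], src = original genome,
#'   dst = derived genome), `breakpoints` (positions in the derived genome)
#'   and `events` (data.frame log).
#' @export
simulateRearrangement <- function(mapLength, nEvents,
                                  eventMix = c(inversion = 0.5,
                                               translocation = 0.5),
                                  minBlock = 10000, seed = 1L,
                                  chrom = "chr1") {
  if (nEvents * 2 * minBlock >= mapLength)
    stop("nEvents * 2 * minBlock must be < mapLength", call. = FALSE)
  segs <- data.frame(src_start = 0, src_end = mapLength, strand = "+")
  events <- data.frame(type = character(), a = numeric(), b = numeric(),
                       c = numeric())
  withSeed(substreamSeed(seed, "rearrangement"), {
    for (ev in seq_len(nEvents)) {
      type <- sample(names(eventMix), 1, prob = eventMix)
      for (try in seq_len(1000)) {
        a <- floor(runif(1, minBlock, mapLength - 2 * minBlock))
        b <- floor(runif(1, a + minBlock, min(mapLength - minBlock,
                                              a + mapLength / 4)))
        cpos <- NA_real_
        if (type == "translocation") {
          cpos <- floor(runif(1, 0, mapLength - (b - a)))
          if (cpos > a - minBlock && cpos < b + minBlock) next
          if (cpos < minBlock || cpos > mapLength - (b - a) - minBlock) next
        }
        # keep every junction at least minBlock from existing junctions
        junc <- cumsum(segs$src_end - segs$src_start)
        junc <- junc[-length(junc)]
        prop <- c(a, b, if (!is.na(cpos)) cpos)
        if (length(junc) &&
            any(vapply(prop, function(p) any(abs(junc - p) < minBlock),
                       logical(1)))) next
        break
      }
      segs <- .applyEvent(segs, type, a, b, cpos)
      events <- rbind(events, data.frame(type = type, a = a, b = b,
                                         c = if (is.na(cpos)) NA else cpos))
    }
  })
  segs <- .mergeCollinear(segs)
  dstEnd <- cumsum(segs$src_end - segs$src_start)
  dstStart <- c(0, head(dstEnd, -1))
  blocks <- data.frame(src_chrom = chrom, src_start = segs$src_start,
                       src_end = segs$src_end, dst_chrom = chrom,
                       dst_start = dstStart, dst_end = dstEnd,
                       strand = segs$strand,
                       score = segs$src_end - segs$src_start)
  bp <- if (nrow(segs) > 1) dstEnd[-length(dstEnd)] else numeric()
  list(map = CoordinateMap(blocks), breakpoints = bp, events = events)
}

# Split the derived-genome segment list at derived position p.
.splitAt <- function(segs, p) {
  lens <- segs$src_end - segs$src_start
  ends <- cumsum(lens)
  starts <- c(0, head(ends, -1))
  if (p %in% c(0, ends)) return(segs)
  k <- which(p > starts & p < ends)[1]
  off <- p - starts[k]
  s <- segs[k, ]
  if (s$strand == "+") {
    first <- data.frame(src_start = s$src_start, src_end = s$src_start + off,
                        strand = "+")
    second <- data.frame(src_start = s$src_start + off, src_end = s$src_end,
                         strand = "+")
  } else {
    first <- data.frame(src_start = s$src_end - off, src_end = s$src_end,
                        strand = "-")
    second <- data.frame(src_start = s$src_start, src_end = s$src_end - off,
                         strand = "-")
  }
  rbind(segs[seq_len(k - 1), ], first, second,
        segs[seq_len(nrow(segs))[-seq_len(k)], ])
}

.applyEvent <- function(segs, type, a, b, cpos) {
  segs <- .splitAt(segs, a)
  segs <- .splitAt(segs, b)
  if (type == "translocation" && !is.na(cpos)) segs <- .splitAt(segs, cpos)
  lens <- segs$src_end - segs$src_start
  ends <- cumsum(lens); starts <- c(0, head(ends, -1))
  inside <- which(starts >= a & ends <= b)
  if (type == "inversion") {
    inv <- segs[rev(inside), ]
    inv$strand <- ifelse(inv$strand == "+", "-", "+")
    segs[inside, ] <- inv
    segs
  } else {
    moved <- segs[inside, ]
    rest <- segs[-inside, ]
    lens2 <- rest$src_end - rest$src_start
    ends2 <- cumsum(lens2); starts2 <- c(0, head(ends2, -1))
    cpos2 <- if (cpos > b) cpos - (b - a) else cpos
    k <- which(cpos2 == starts2)
    if (!length(k)) k <- which(cpos2 > starts2 & cpos2 <= ends2)[1] + 1L
    rbind(rest[seq_len(k - 1), ], moved,
          rest[seq_len(nrow(rest))[-seq_len(k - 1)], ])
  }
}

# Merge adjacent derived segments that are collinear on the source (an event
# sequence can recreate adjacency); keeps true breakpoints honest.
.mergeCollinear <- function(segs) {
  if (nrow(segs) < 2) return(segs)
  out <- segs[1, ]
  for (k in 2:nrow(segs)) {
    last <- out[nrow(out), ]
    cur <- segs[k, ]
    if (last$strand == cur$strand &&
        ((cur$strand == "+" && last$src_end == cur$src_start) ||
         (cur$strand == "-" && cur$src_end == last$src_start))) {
      out[nrow(out), "src_start"] <- min(last$src_start, cur$src_start)
      out[nrow(out), "src_end"] <- max(last$src_end, cur$src_end)
    } else out <- rbind(out, cur)
  }
  rownames(out) <- NULL
  out
}
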
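#' Default parameters for the annotation simulator
#'
#' @param ctcfAtBoundaryProb probability that a boundary hosts a CTCF peak.
#' @param ctcfBackgroundN number of background CTCF peaks placed uniformly.
#' @param peakWidth CTCF peak width in bp.
#' @param teFamilySpec data.frame with columns `family`, `class`,
#'   `n_background`, `width` describing transposable-element families and
#'   their genome-wide background counts.
#' @param teOldFamily,teYoungFamily families preferentially planted at CTCF
#'   sites inside ultraconserved and reference-specific boundaries.
#' @param tePlantOdds planting odds; a boundary CTCF peak in the targeted
#'   group receives a planted TE with probability `1 - 1/tePlantOdds`
#'   (odds 1 disables planting and leaves TEs uniform, the null
#'   configuration).
#' @param geneDensity genes per bp (mean gene width 30 kb).
#' @param geneAtBoundaryProb probability that a boundary is made to overlap a
#'   gene (gives labelled groups a realistic gene-overlap structure).
#' @param gcWindow,gcHeterogeneity GC track window (bp) and spatial
#'   amplitude of the smoothed GC field around the 0.41 genomic mean.
#' @param stateMeanLen mean chromatin-state segment length (bp).
#' @param cnvPCase,cnvPControl per-boundary deletion probabilities in the
#'   case and control cohorts for reference-specific boundaries.
#' @param cnvBackgroundN background deletions per cohort.
#' @return A list of class `AnnotationParams`.
#' @export
annotationParams <- function(ctcfAtBoundaryProb = 0.45,
                             ctcfBackgroundN = 100,
                             peakWidth = 200,
                             teFamilySpec = data.frame(
                               family = c("MIR", "B2", "L1", "ERVK"),
                               class = c("SINE", "SINE", "LINE", "LTR"),
                               n_background = c(150, 150, 100, 100),
                               width = c(200, 200, 1000, 600)),
                             teOldFamily = "MIR", teYoungFamily = "ERVK",
                             tePlantOdds = 5,
                             geneDensity = 1 / 60000,
                             geneAtBoundaryProb = 0.6,
                             gcWindow = 1000, gcHeterogeneity = 0.06,
                             stateMeanLen = 5000,
                             cnvPCase = 0.30, cnvPControl = 0.14,
                             cnvBackgroundN = 50) {
  stopifnot(ctcfAtBoundaryProb >= 0, ctcfAtBoundaryProb <= 1,
            tePlantOdds >= 1, cnvPCase >= 0, cnvPCase <= 1,
            cnvPControl >= 0, cnvPControl <= 1)
  structure(as.list(environment()), class = "AnnotationParams")
}

.uniformIntervals <- function(n, genomeLength, width, chrom = "chr1") {
  if (n <= 0) return(GRanges())
  st <- floor(runif(n, 0, pmax(1, genomeLength - width)))
  sort(GRanges(chrom, IRanges(st + 1, st + width)))
}

#' Simulate annotation tracks around labeled boundaries
#'
#' Generates every annotation the downstream statistics consume, with
#' planted structure controlled by [annotationParams()]: CTCF peaks at
#' boundaries plus uniform background; TE intervals with class/family labels
#' where an "old" family preferentially overlaps CTCF sites in
#' ultraconserved boundaries and a "young" family those in
#' reference-specific boundaries; genes; a spatially smooth GC track;
#' chromatin-state segments; and case/control deletion CNVs with elevated
#' recurrence at reference-specific boundaries in cases.
#'
#' @param boundaries `GRanges` of boundaries with a `label` metadata column
#'   (conservation labels as from [labelFromPresence()]).
#' @param genomeLength genome length in bp.
#' @param params an [annotationParams()].
#' @param seed integer master seed.
#' @param chrom chromosome name.
#' @return list of class `AnnotationSet` with elements `ctcf`, `te`,
#'   `genes`, `gc`, `states`, `cnvCase`, `cnvControl` (all `GRanges`).
#' @export
simulateAnnotations <- function(boundaries, genomeLength,
                                params = annotationParams(), seed = 1L,
                                chrom = "chr1") {
  stopifnot(inherits(params, "AnnotationParams"))
  labels <- mcols(boundaries)$label
  if (is.null(labels)) labels <- rep("other", length(boundaries))
  withSeed(substreamSeed(seed, "annotations"), {
    ## CTCF peaks
    hasPeak <- runif(length(boundaries)) < params$ctcfAtBoundaryProb
    pw <- params$peakWidth
    peakStart <- floor(start(boundaries[hasPeak]) - 1 +
                         runif(sum(hasPeak)) *
                         pmax(1, width(boundaries[hasPeak]) - pw))
    ctcf <- c(GRanges(chrom, IRanges(peakStart + 1, peakStart + pw)),
              .uniformIntervals(params$ctcfBackgroundN, genomeLength, pw,
                                chrom))
    ctcf <- sort(ctcf)
    mcols(ctcf)$name <- sprintf("ctcf_%d", seq_along(ctcf))

    ## TE intervals: uniform background per family + planted copies
    spec <- params$teFamilySpec
    te <- GRanges()
    for (k in seq_len(nrow(spec))) {
      g <- .uniformIntervals(spec$n_background[k], genomeLength,
                             spec$width[k], chrom)
      if (length(g)) {
        mcols(g)$class <- spec$class[k]
        mcols(g)$family <- spec$family[k]
        te <- c(te, g)
      }
    }
    plantProb <- 1 - 1 / params$tePlantOdds
    if (plantProb > 0) {
      plantAt <- function(targetLabel, family) {
        idx <- which(labels == targetLabel)
        if (!length(idx)) return(GRanges())
        bsel <- boundaries[idx]
        hits <- findOverlaps(ctcf, bsel)
        pk <- ctcf[unique(queryHits(hits))]
        pk <- pk[runif(length(pk)) < plantProb]
        if (!length(pk)) return(GRanges())
        w <- spec$width[spec$family == family][1]
        cls <- spec$class[spec$family == family][1]
        st <- pmax(0, floor((start(pk) + end(pk)) / 2 - w / 2))
        g <- GRanges(chrom, IRanges(st + 1, st + w))
        mcols(g)$class <- cls
        mcols(g)$family <- family
        g
      }
      te <- c(te, plantAt("ultraconserved", params$teOldFamily))
      for (lab in grep("_specific$", unique(labels), value = TRUE))
        te <- c(te, plantAt(lab, params$teYoungFamily))
    }
    te <- sort(te)

    ## genes: uniform background plus boundary-overlapping genes
    nGenes <- rpois(1, params$geneDensity * genomeLength)
    gw <- pmax(2000, round(rexp(nGenes, 1 / 30000)))
    gst <- floor(runif(nGenes, 0, pmax(1, genomeLength - gw)))
    genes <- GRanges(chrom, IRanges(gst + 1, gst + gw))
    atB <- which(runif(length(boundaries)) < params$geneAtBoundaryProb)
    if (length(atB)) {
      bw <- pmax(2000, round(rexp(length(atB), 1 / 30000)))
      bst <- pmax(0, start(boundaries[atB]) - 1 - floor(bw / 2))
      genes <- c(genes, GRanges(chrom, IRanges(bst + 1, bst + bw)))
    }
    genes <- sort(genes)
    mcols(genes)$name <- sprintf("gene_%d", seq_along(genes))

    ## GC track: smoothed gaussian field around 0.41
    nw <- ceiling(genomeLength / params$gcWindow)
    raw <- rnorm(nw)
    sm <- stats::filter(raw, rep(1 / 21, 21), circular = TRUE)
    gcv <- pmin(0.75, pmax(0.25,
                           0.41 + params$gcHeterogeneity *
                             as.numeric(sm) / stats::sd(as.numeric(sm))))
    gcStart <- (seq_len(nw) - 1) * params$gcWindow
    gc <- GRanges(chrom, IRanges(gcStart + 1,
                                 pmin(gcStart + params$gcWindow,
                                      genomeLength)))
    mcols(gc)$score <- gcv

    ## chromatin states: iid segments with exponential lengths
    stateNames <- c("TSS", "Enhancer", "Transcription", "CTCF", "Quiescent")
    stateProb <- c(0.05, 0.12, 0.23, 0.10, 0.50)
    segLen <- numeric(); tot <- 0
    while (tot < genomeLength) {
      l <- max(500, round(rexp(1, 1 / params$stateMeanLen)))
      segLen <- c(segLen, min(l, genomeLength - tot))
      tot <- tot + l
    }
    segEnd <- cumsum(segLen)
    segStart <- c(0, head(segEnd, -1))
    states <- GRanges(chrom, IRanges(segStart + 1,
                                     pmin(segEnd, genomeLength)))
    mcols(states)$state <- sample(stateNames, length(states), replace = TRUE,
                                  prob = stateProb)

    ## CNVs: per-cohort deletions hitting reference-specific boundaries
    ssIdx <- grep("_specific$", labels)
    makeCnv <- function(p, tag) {
      del <- ssIdx[runif(length(ssIdx)) < p]
      g <- GRanges()
      if (length(del)) {
        ext <- floor(runif(length(del), 5000, 50000))
        st <- pmax(0, start(boundaries[del]) - 1 - ext)
        en <- pmin(genomeLength, end(boundaries[del]) + ext)
        g <- GRanges(chrom, IRanges(st + 1, en))
      }
      g <- c(g, .uniformIntervals(params$cnvBackgroundN, genomeLength,
                                  30000, chrom))
      g <- sort(g)
      if (length(g)) mcols(g)$name <- sprintf("%s_%d", tag, seq_along(g))
      g
    }
    cnvCase <- makeCnv(params$cnvPCase, "case")
    cnvControl <- makeCnv(params$cnvPControl, "ctrl")

    structure(list(ctcf = ctcf, te = te, genes = genes, gc = gc,
                   states = states, cnvCase = cnvCase,
                   cnvControl = cnvControl),
              class = "AnnotationSet")
  })
}
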
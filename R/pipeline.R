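#' Default run configuration
#'
#' Returns the full default configuration for [runStage()]/[runDemo()]:
#' every stage parameter with its default, a global seed and the output
#' directory. Values loaded from a YAML file override the defaults; unknown
#' keys are rejected before any stage runs.
#'
#' @param ... named overrides.
#' @param file optional YAML file of overrides.
#' @return A named list of class `RunConfig`.
#' @export
runConfig <- function(..., file = NULL) {
  cfg <- list(
    seed = 1L, out_dir = "tadevol_out",
    genome_length = 3e7, bin_size = 10000,
    n_boundaries_root = 55, gain_rate = 8e-9, loss_rate = 0.01,
    boundary_width = 10000, min_separation = 150000,
    decay_exponent = 1, base_count = 100, noise = "poisson",
    min_depth = 100000, max_depth = 600000, window_step = 50000,
    min_delta = 0.01, q_threshold = 0.05,
    min_match = 0.95, merge_distance = 10000,
    strict_order_conservation = TRUE,
    n_rearrangements = 5, min_block = 50000,
    bos_flank = 1000, dup_ratio = 0.10, max_gap = 1e6,
    n_random_sets = 10, n_strata = 10, n_perm = 100,
    pileup_flank = 1e6)
  over <- list(...)
  if (!is.null(file)) over <- utils::modifyList(yaml::read_yaml(file), over)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  cfg <- utils::modifyList(cfg, over)
  if (!cfg$noise %in% c("poisson", "none"))
    stop("config 'noise' must be 'poisson' or 'none'", call. = FALSE)
  for (key in c("genome_length", "bin_size", "merge_distance", "n_perm"))
    assertScalarNumber(cfg[[key]], key, lower = 0)
  structure(cfg, class = c("RunConfig", "list"))
}

.stageLog <- function(stage, msg) {
  message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run one pipeline stage
#'
#' Thin file-level driver over the package functions. Each stage reads and
#' writes only the documented plain-text formats (BED, bedGraph, COO matrix
#' text, chain, TSV). `stage = "demo"` runs the full synthetic
#' demonstration via [runDemo()].
#'
#' @param stage one of `"simulate"`, `"insulation"`, `"call-tads"`,
#'   `"liftover"`, `"union"`, `"classify"`, `"bos"`, `"enrich"`, `"demo"`.
#' @param config a [runConfig()] (or list of overrides).
#' @param inputs named list of input file paths, as documented per stage in
#'   the vignette.
#' @return Invisibly, a named list of the paths written.
#' @export
runStage <- function(stage, config = runConfig(), inputs = list()) {
  stage <- match.arg(stage, c("simulate", "insulation", "call-tads",
                              "liftover", "union", "classify", "bos",
                              "enrich", "demo"))
  if (!inherits(config, "RunConfig")) config <- do.call(runConfig, config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  p <- function(...) file.path(config$out_dir, paste0(...))
  if (stage == "demo") return(runDemo(config$seed, config$out_dir, config))
  if (stage == "simulate") {
    sim <- simulateBoundaryEvolution(defaultPhylogeny(),
      evolutionParams(config$n_boundaries_root, config$gain_rate,
                      config$loss_rate, config$genome_length,
                      config$boundary_width, config$min_separation),
      seed = config$seed)
    for (tx in names(sim$boundaries))
      out[[paste0("bed_", tx)]] <-
        writeBed(sim$boundaries[[tx]], p("boundaries_", tx, ".bed"))
    write.table(sim$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$truth <- p("truth.tsv")
    for (tx in names(sim$boundaries)) {
      cm <- simulateContactMatrix(sim$boundaries[[tx]],
        config$genome_length, config$bin_size, config$decay_exponent,
        config$base_count, config$noise,
        seed = substreamSeed(config$seed, tx))
      out[[paste0("matrix_", tx)]] <-
        writeMatrixCOO(cm, p("matrix_", tx, ".coo"))
    }
    .stageLog(stage, sprintf("%d taxa simulated", length(sim$boundaries)))
  } else if (stage == "insulation") {
    cm <- readMatrixCOO(inputs$matrix)
    tr <- insulationTrack(cm, config$min_depth, config$max_depth,
                          config$window_step)
    gr <- GRanges(chrom(tr), IRanges(seq_len(nbins(tr)) * binSize(tr) -
                                       binSize(tr) + 1,
                                     seq_len(nbins(tr)) * binSize(tr)))
    mcols(gr)$score <- score(tr)
    out$track <- writeBedGraph(gr[!is.na(score(tr))], p("insulation.bedgraph"))
  } else if (stage == "call-tads") {
    cm <- readMatrixCOO(inputs$matrix)
    tr <- insulationTrack(cm, config$min_depth, config$max_depth,
                          config$window_step)
    calls <- callBoundaries(tr, cm, config$min_delta, config$q_threshold)
    mcols(calls)$name <- sprintf("b%d", seq_along(calls))
    out$calls <- writeBed(calls, p("boundaries.bed"),
                          extraCols = c("delta", "qvalue"))
  } else if (stage == "liftover") {
    iv <- readBed(inputs$bed)
    lifted <- liftIntervals(iv, readChain(inputs$chain), config$min_match)
    out$lifted <- writeBed(lifted$lifted, p("lifted.bed"))
    writeLines(as.character(lifted$failed), p("failed_ids.txt"))
    out$failed <- p("failed_ids.txt")
  } else if (stage == "union") {
    sets <- lapply(inputs$beds, readBed)
    un <- buildUnion(sets, config$merge_distance)
    out$union <- .writeUnion(un, p("union.tsv"))
  } else if (stage == "classify") {
    un <- .readUnion(inputs$union)
    phylo <- defaultPhylogeny()
    un <- classifyConservation(un, phylo$clades, phylo$refs,
      mergeDistance = config$merge_distance,
      strictOrderConservation = config$strict_order_conservation)
    out$union <- .writeUnion(un, p("union_labeled.tsv"))
    nw <- attr(un, "nWayTable")
    write.table(data.frame(n_way = names(nw), count = as.integer(nw)),
                p("nway_histogram.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$nway <- p("nway_histogram.tsv")
  } else if (stage == "bos") {
    map <- readChain(inputs$chain)
    blocks <- elongateBlocks(map, maxGap = config$max_gap)
    sizes <- stats::setNames(config$genome_length,
                             unique(blocks$src_chrom)[1])
    bos <- defineBOS(blocks, config$bos_flank, sizes)
    out$bos <- writeBed(bos, p("bos.bed"), extraCols = "status")
  } else if (stage == "enrich") {
    # boundary BED carries the conservation label in the name column
    boundaries <- readBed(inputs$boundaries)
    mcols(boundaries)$label <- mcols(boundaries)$name
    res <- cnvRecurrenceTest(boundaries, readBed(inputs$cnv_case),
                             readBed(inputs$cnv_control))
    write.table(res, p("cnv_test.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    out$cnv <- p("cnv_test.tsv")
  }
  invisible(out)
}

.writeUnion <- function(un, path) {
  df <- data.frame(chrom = as.character(seqnames(un)),
                   start = start(un) - 1, end = end(un),
                   as.data.frame(mcols(un)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.readUnion <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE)
  un <- GRanges(df$chrom, IRanges(df$start + 1, df$end))
  for (col in setdiff(names(df), c("chrom", "start", "end")))
    mcols(un)[[col]] <- df[[col]]
  un
}

#' End-to-end synthetic demonstration run
#'
#' From a single seed: simulates boundary evolution on the default 8-taxon
#' phylogeny, builds per-taxon contact matrices with planted insulation,
#' computes insulation tracks and calls boundaries, lifts the calls to the
#' reference, builds and classifies the union table, simulates annotations
#' and runs the group summary, CNV and TE statistics, simulates a
#' rearranged genome and runs the BOS detection and permutation tests, and
#' writes every artifact plus a JSON manifest and a label-recovery report
#' comparing predicted conservation labels to the simulated truth. Output
#' is byte-identical across repeated runs with the same seed.
#'
#' @param seed integer master seed.
#' @param outDir output directory.
#' @param config a [runConfig()].
#' @return Invisibly, a list with the labeled union table, the truth table,
#'   the recovery report and the statistical test results.
#' @export
runDemo <- function(seed = 1L, outDir = "tadevol_demo",
                    config = runConfig(seed = seed)) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outDir, paste0(...))
  phylo <- defaultPhylogeny()
  .stageLog("demo", "simulating boundary evolution")
  sim <- simulateBoundaryEvolution(phylo,
    evolutionParams(config$n_boundaries_root, config$gain_rate,
                    config$loss_rate, config$genome_length,
                    config$boundary_width, config$min_separation),
    seed = seed)
  write.table(sim$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  .stageLog("demo", "simulating matrices and calling boundaries")
  calls <- list()
  tracks <- list()
  for (tx in phylo$taxa) {
    cm <- simulateContactMatrix(sim$boundaries[[tx]], config$genome_length,
      config$bin_size, config$decay_exponent, config$base_count,
      config$noise, seed = substreamSeed(seed, tx))
    tr <- insulationTrack(cm, config$min_depth, config$max_depth,
                          config$window_step)
    tracks[[tx]] <- tr
    calls[[tx]] <- callBoundaries(tr, cm, config$min_delta,
                                  config$q_threshold)
    writeBed(calls[[tx]], p("calls_", tx, ".bed"))
  }
  # identity liftover to the reference (shared coordinate space)
  idMap <- identityMap(config$genome_length)
  lifted <- lapply(calls, function(g)
    liftIntervals(g, idMap, config$min_match)$lifted)
  un <- buildUnion(lifted, config$merge_distance)
  un <- classifyConservation(un, phylo$clades, phylo$refs,
    mergeDistance = config$merge_distance,
    strictOrderConservation = config$strict_order_conservation)
  # reference insulation score per union row (human track at the midpoint)
  refTrack <- tracks[[phylo$refs[1]]]
  midBin <- pmin(pmax(floor((start(un) - 1 + end(un)) / 2 /
                              config$bin_size) + 1, 1), nbins(refTrack))
  mcols(un)$score <- score(refTrack)[midBin]
  .writeUnion(un, p("union_labeled.tsv"))
  recovery <- labelRecovery(un, sim$truth, config$merge_distance,
                            scoredRange = c(config$max_depth,
                                            config$genome_length -
                                              config$max_depth))
  write.table(recovery$table, p("label_recovery.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  .stageLog("demo", "annotations and enrichment statistics")
  truthGr <- GRanges("chr1", IRanges(sim$truth$pos + 1,
                                     sim$truth$pos + config$boundary_width))
  mcols(truthGr)$label <- sim$truth$label
  ann <- simulateAnnotations(truthGr, config$genome_length, seed = seed)
  writeBed(ann$ctcf, p("ctcf.bed"))
  writeBed(ann$te, p("te.bed"), extraCols = c("class", "family"))
  writeBed(ann$genes, p("genes.bed"))
  writeBedGraph(ann$gc, p("gc.bedgraph"))
  gs <- groupSummary(un, ann$genes, ann$ctcf, phylo$refs[1])
  write.table(gs$summary, p("group_summary.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  te <- teCtcfEnrichment(truthGr, ann$ctcf, ann$te, config$genome_length)
  write.table(te, p("te_enrichment.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  ss <- truthGr[grepl("_specific$", mcols(truthGr)$label)]
  cnv <- if (length(ss))
    cnvRecurrenceTest(ss, ann$cnvCase, ann$cnvControl) else NULL
  if (!is.null(cnv))
    write.table(cnv, p("cnv_test.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  .stageLog("demo", "synteny breakpoints")
  rea <- simulateRearrangement(config$genome_length,
    config$n_rearrangements, minBlock = config$min_block, seed = seed)
  blocks <- elongateBlocks(rea$map, maxGap = config$max_gap)
  sizes <- stats::setNames(config$genome_length, "chr1")
  bos <- defineBOS(blocks, config$bos_flank, sizes)
  writeBed(bos, p("bos.bed"), extraCols = "status")
  rnd <- gcStratifiedSample(bos, ann$gc, config$n_random_sets,
                            config$n_strata, seed = seed)
  bosTest <- bosBoundaryOverlapTest(bos, truthGr, rnd)
  write.table(bosTest, p("bos_overlap_test.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("tadevol")),
                   config = unclass(config),
                   n_taxa = length(phylo$taxa),
                   n_true_boundaries = nrow(sim$truth),
                   n_union_rows = length(un))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA), p("manifest.json"))
  invisible(list(union = un, truth = sim$truth, recovery = recovery,
                 groupSummary = gs, te = te, cnv = cnv, bos = bosTest,
                 calls = calls, tracks = tracks))
}

#' Compare predicted union labels to simulated truth
#'
#' Matches each true boundary (by position) to the union row overlapping it
#' within `tol` bp and tabulates predicted against true labels.
#'
#' @param union labeled union `GRanges`.
#' @param truth truth data.frame from [simulateBoundaryEvolution()].
#' @param tol matching tolerance in bp.
#' @param scoredRange optional numeric `c(lo, hi)`: only truth boundaries
#'   with `lo <= pos <= hi` are scored (used to restrict recovery to the
#'   chromosome extent where the insulation score is defined).
#' @return list with `table` (true label, predicted label, n) and
#'   `perLabel` (recovery fraction per true label).
#' @export
labelRecovery <- function(union, truth, tol = 10000, scoredRange = NULL) {
  if (!is.null(scoredRange))
    truth <- truth[truth$pos >= scoredRange[1] & truth$pos <= scoredRange[2], ]
  truthGr <- GRanges("chr1", IRanges(truth$pos + 1, truth$pos + 1))
  hits <- findOverlaps(truthGr, union + tol, select = "first")
  pred <- ifelse(is.na(hits), "missed", mcols(union)$label[hits])
  tab <- as.data.frame(table(true = truth$label, predicted = pred))
  tab <- tab[tab$Freq > 0, ]
  names(tab)[3] <- "n"
  perLabel <- vapply(unique(truth$label), function(l) {
    i <- truth$label == l
    mean(pred[i] == l)
  }, numeric(1))
  list(table = tab, perLabel = perLabel)
}
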
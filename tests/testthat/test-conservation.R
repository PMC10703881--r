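test_that("liftover through the identity map is the identity", {
  iv <- GRanges("chr1", IRanges(c(101, 5001), c(600, 6000)))
  mcols(iv)$name <- c("a", "b")
  res <- liftIntervals(iv, identityMap(10000))
  expect_length(res$failed, 0)
  expect_equal(start(res$lifted), start(iv))
  expect_equal(end(res$lifted), end(iv))
  expect_equal(mcols(res$lifted)$name, c("a", "b"))
})

test_that("an interval straddling a large map gap fails to lift", {
  blocks <- data.frame(
    src_chrom = "chr1", src_start = c(0, 6000), src_end = c(5000, 10000),
    dst_chrom = "chrQ", dst_start = c(0, 5000), dst_end = c(5000, 9000),
    strand = "+", score = 1)
  map <- CoordinateMap(blocks)
  # 4900-5900: 1000 bp, only 100 bp of it maps (on one side); fails at 0.95
  bad <- GRanges("chr1", IRanges(4901, 5900))
  res <- liftIntervals(bad, map)
  expect_equal(res$failed, 1L)
  # fully inside one block: lifts
  ok <- GRanges("chr1", IRanges(1001, 2000))
  res2 <- liftIntervals(ok, map)
  expect_length(res2$failed, 0)
  expect_equal(start(res2$lifted) - 1, 1000)
})

test_that("lifting through an inverted block matches the per-base oracle", {
  blocks <- data.frame(
    src_chrom = "chr1", src_start = 2000, src_end = 8000,
    dst_chrom = "chrQ", dst_start = 1000, dst_end = 7000,
    strand = "-", score = 1)
  map <- CoordinateMap(blocks)
  iv <- GRanges("chr1", IRanges(3001, 4000))
  res <- liftIntervals(iv, map)
  expect_length(res$failed, 0)
  mapped <- vapply(3000:3999, function(x)
    oracleMapBase(blocks, x)$pos, numeric(1))
  expect_equal(start(res$lifted) - 1, min(mapped))
  expect_equal(end(res$lifted), max(mapped) + 1)
})

test_that("liftover agrees with rtracklayer on plus and minus chains", {
  blocks <- data.frame(
    src_chrom = "chr1", src_start = c(0, 5000), src_end = c(4000, 9000),
    dst_chrom = "chrQ", dst_start = c(100, 6000), dst_end = c(4100, 10000),
    strand = c("+", "-"), score = c(5, 5))
  map <- CoordinateMap(blocks)
  f <- withr::local_tempfile(fileext = ".chain")
  writeChain(map, f, dstSizes = c(chrQ = 20000))
  ch <- rtracklayer::import.chain(f)
  iv <- GRanges("chr1", IRanges(c(1001, 6001), c(1500, 6500)))
  lifted <- liftIntervals(iv, map)$lifted
  rtl <- unlist(rtracklayer::liftOver(iv, ch))
  expect_equal(start(lifted), start(rtl))
  expect_equal(end(lifted), end(rtl))
  expect_equal(as.character(seqnames(lifted)), as.character(seqnames(rtl)))
})

test_that("union merging follows bedtools-style single linkage", {
  mk <- function(s, e) GRanges("chr1", IRanges(s + 1, e))
  # 5 kb gap: one union row present in both species
  un <- buildUnion(list(A = mk(100000, 110000), B = mk(115000, 125000)))
  expect_length(un, 1)
  expect_true(mcols(un)$present.A & mcols(un)$present.B)
  expect_equal(mcols(un)$n_way, 2)
  # 11 kb gap: two rows
  un2 <- buildUnion(list(A = mk(100000, 110000), B = mk(121000, 131000)))
  expect_length(un2, 2)
  # chained triple, pairwise 8 kb gaps: single linkage joins all three
  un3 <- buildUnion(list(A = mk(0, 10000), B = mk(18000, 28000),
                         C = mk(36000, 46000)))
  expect_length(un3, 1)
  expect_equal(mcols(un3)$n_way, 3)
})

test_that("union equals transitive-closure clustering on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 40
    s <- sort(sample.int(5e5, n))
    e <- s + sample(2000:12000, n, replace = TRUE)
    sp <- sample(c("A", "B", "C"), n, replace = TRUE)
    sets <- lapply(split(seq_len(n), sp), function(i)
      GRanges("chr1", IRanges(s[i] + 1, e[i])))
    un <- buildUnion(sets, mergeDistance = 10000)
    expect_length(un, length(unique(oracleCluster(s, e, 10000))))
  }
})

test_that("union construction is order-invariant and idempotent", {
  set.seed(4)
  mk <- function(k) {
    st <- sort(sample.int(1e6, k))
    GRanges("chr1", IRanges(st + 1, st + 8000))
  }
  sets <- list(A = mk(20), B = mk(15), C = mk(25))
  u1 <- buildUnion(sets)
  u2 <- buildUnion(rev(sets))
  expect_equal(granges(u1), granges(u2))
  expect_equal(mcols(u1)$n_way, mcols(u2)$n_way)
  # idempotence: union of the union spans is itself
  again <- buildUnion(list(X = granges(u1)))
  expect_equal(granges(again), granges(u1))
})

test_that("conservation labels follow the grouping definitions", {
  taxa <- c("human", "nomascus", "hylobates", "rhesus",
            "mouse", "caroli", "pahari", "rat")
  clades <- list(primate = taxa[1:4], rodent = taxa[5:8])
  mkUnion <- function(presList, starts) {
    un <- GRanges("chr1", IRanges(starts + 1, starts + 10000))
    for (k in seq_along(taxa))
      mcols(un)[[paste0("present.", taxa[k])]] <-
        vapply(presList, function(p) p[k] == 1, logical(1))
    mcols(un)$n_way <- vapply(presList, sum, numeric(1))
    un
  }
  un <- mkUnion(list(c(1,1,1,1,1,1,1,1), c(1,1,1,1,0,0,0,0),
                     c(0,0,0,0,1,1,1,1), c(1,0,0,0,0,0,0,0),
                     c(0,0,0,0,1,0,0,0), c(1,0,1,0,0,0,0,1)),
                starts = c(0, 1e5, 2e5, 3e5, 4e5, 5e5) * 1)
  lab <- classifyConservation(un, clades, c("human", "mouse"))
  expect_equal(mcols(lab)$label,
               c("ultraconserved", "primate_conserved", "rodent_conserved",
                 "human_specific", "mouse_specific", "other"))
  nw <- attr(lab, "nWayTable")
  expect_equal(sum(nw), 6)
  expect_equal(as.integer(nw[["8"]]), 1)

  # outgroup exclusion: human-only row near a chimp boundary becomes other
  chimp <- GRanges("chr1", IRanges(3e5 + 15000, 3e5 + 25000))
  lab2 <- classifyConservation(un, clades, c("human", "mouse"),
                               exclusionSets = list(chimp))
  expect_equal(mcols(lab2)$label[4], "other")

  # loose order conservation admits partial clades
  un3 <- mkUnion(list(c(1,1,0,0,0,0,0,0)), starts = 0)
  strict <- classifyConservation(un3, clades, c("human", "mouse"))
  loose <- classifyConservation(un3, clades, c("human", "mouse"),
                                strictOrderConservation = FALSE)
  expect_equal(mcols(strict)$label, "other")
  expect_equal(mcols(loose)$label, "primate_conserved")

  # unknown species rejected
  mcols(un3)$present.gorilla <- TRUE
  expect_error(classifyConservation(un3, clades, c("human", "mouse")),
               "gorilla")
})

test_that("classification reproduces simulated truth under perfect liftover", {
  phylo <- defaultPhylogeny()
  sim <- simulateBoundaryEvolution(phylo, evolutionParams(60), seed = 23)
  un <- buildUnion(sim$boundaries)
  un <- classifyConservation(un, phylo$clades, phylo$refs)
  rec <- labelRecovery(un, sim$truth)
  expect_true(all(rec$perLabel == 1))
})

test_that("group score comparisons use the exact rank-sum distribution", {
  taxa <- c("human", "mouse")
  un <- GRanges("chr1", IRanges(seq(1, by = 1e5, length.out = 6), width = 1e4))
  mcols(un)$present.human <- TRUE
  mcols(un)$present.mouse <- FALSE
  mcols(un)$n_way <- 1
  mcols(un)$label <- rep(c("ultraconserved", "human_specific"), each = 3)
  mcols(un)$score <- c(1, 2, 3, 4, 5, 6)
  gs <- groupSummary(un, genes = GRanges(), ctcf = GRanges(), "human")
  row <- gs$wilcoxon[gs$wilcoxon$group1 == "human_specific" &
                       gs$wilcoxon$group2 == "ultraconserved", ]
  # {4,5,6} vs {1,2,3}: W = 9 one way, exact two-sided p = 0.1
  expect_equal(row$p, 0.1)
  # identical distributions: p = 1
  mcols(un)$score <- c(1, 2, 3, 1, 2, 3)
  gs2 <- groupSummary(un, GRanges(), GRanges(), "human")
  row2 <- gs2$wilcoxon[gs2$wilcoxon$group1 == "human_specific" &
                         gs2$wilcoxon$group2 == "ultraconserved", ]
  expect_equal(row2$p, 1)
})

test_that("group summary reports counts, fractions and annotations", {
  un <- GRanges("chr1", IRanges(seq(1, by = 1e5, length.out = 10),
                                width = 1e4))
  mcols(un)$present.human <- c(rep(TRUE, 8), FALSE, FALSE)
  mcols(un)$present.mouse <- TRUE
  mcols(un)$n_way <- 2
  mcols(un)$label <- c(rep("ultraconserved", 4), rep("other", 6))
  mcols(un)$score <- seq(-1, 0.8, length.out = 10)
  genes <- GRanges("chr1", IRanges(1, 5000))       # overlaps row 1 only
  ctcf <- GRanges("chr1", IRanges(c(100, 200), width = 50))
  gs <- groupSummary(un, genes, ctcf, "human")
  s <- gs$summary
  expect_equal(sum(s$n), 8)
  expect_equal(s$fraction, s$n / 8)
  uc <- s[s$label == "ultraconserved", ]
  expect_equal(uc$gene_overlap_frac, 0.25)
  expect_equal(uc$ctcf_frac, 0.25)
  expect_equal(uc$ctcf_per_boundary, 0.5)
})

test_that("matched permutation p-values behave at the extremes", {
  pool <- makeBoundaryPool(300)
  un <- pool
  mcols(un)$present.human <- TRUE
  mcols(un)$n_way <- 1
  sc <- mcols(un)$score
  # make the group the pool's lowest-scoring gene-overlapping members
  lab <- rep("other", length(un))
  lowest <- order(sc)[1:20]
  lab[lowest] <- "ultraconserved"
  mcols(un)$label <- lab
  genes <- un[mcols(un)$geneOverlap]
  res <- matchedInsulationPermutation(un, "ultraconserved", genes, "human",
                                      nPerm = 200, seed = 5)
  expect_lte(res$p, 2 / 201)
  expect_error(matchedInsulationPermutation(un, "ultraconserved", genes,
                                            "human", nPerm = 0), "nPerm")
  expect_error(matchedInsulationPermutation(un, "absent_label", genes,
                                            "human"), "empty group")
})
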
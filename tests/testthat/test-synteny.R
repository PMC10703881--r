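blockRow <- function(ss, se, ds, de, strand = "+", score = 150000,
                     src = "chr1", dst = "chrQ") {
  data.frame(src_chrom = src, src_start = ss, src_end = se,
             dst_chrom = dst, dst_start = ds, dst_end = de,
             strand = strand, score = score)
}

test_that("a lone qualifying block elongates to itself", {
  map <- CoordinateMap(blockRow(10000, 15000, 0, 5000))
  out <- elongateBlocks(map)
  expect_equal(nrow(out), 1)
  expect_equal(out$src_start, 10000)
  expect_equal(out$src_end, 15000)
  expect_equal(out$members, "1")
})

test_that("blocks failing the seed filters produce no synteny block", {
  # 900 bp is below the >1 kb length filter despite a high score
  map <- CoordinateMap(blockRow(10000, 10900, 0, 900, score = 200000))
  expect_equal(nrow(elongateBlocks(map)), 0)
  # long but low score
  map2 <- CoordinateMap(blockRow(10000, 20000, 0, 10000, score = 50000))
  expect_equal(nrow(elongateBlocks(map2)), 0)
  # a seed absorbs a small low-score neighbour
  map3 <- CoordinateMap(rbind(blockRow(0, 5000, 0, 5000),
                              blockRow(5200, 5500, 5100, 5400,
                                       score = 10)))
  out3 <- elongateBlocks(map3)
  expect_equal(nrow(out3), 1)
  expect_equal(out3$src_end, 5500)
})

test_that("chaining matches the exhaustive oracle on random instances", {
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(20:60, 1)
    ss <- sort(sample.int(2e6, n))
    len <- sample(200:3000, n, replace = TRUE)
    se <- pmin(ss + len, c(ss[-1], 2.1e6))
    ok <- se > ss
    ss <- ss[ok]; se <- se[ok]; n <- sum(ok)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    dstart <- abs(ss + sample(-20000:20000, n, replace = TRUE))
    blocks <- data.frame(src_chrom = "chr1", src_start = ss, src_end = se,
                         dst_chrom = sample(c("q1", "q2"), n, replace = TRUE),
                         dst_start = dstart, dst_end = dstart + (se - ss),
                         strand = strand,
                         score = sample(c(1e3, 2e5), n, replace = TRUE))
    got <- elongateBlocks(CoordinateMap(blocks), maxGap = 50000)
    want <- oracleChains(blocks, 1000, 100000, 50000)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      cols <- c("src_start", "src_end", "dst_start", "dst_end", "strand")
      expect_equal(got[, cols], want[, cols], ignore_attr = TRUE)
    }
    # output blocks never overlap on the source
    if (nrow(got) > 1) {
      o <- order(got$src_start)
      expect_true(all(got$src_start[o][-1] >= got$src_end[o][-nrow(got)]))
    }
  }
})

test_that("BOS flanks are 1 kb regions clipped at chromosome ends", {
  blocks <- data.frame(src_chrom = "chr1", src_start = 10000,
                       src_end = 50000, dst_chrom = "q", dst_start = 0,
                       dst_end = 40000, strand = "+", score = 2e5,
                       members = "1")
  bos <- defineBOS(blocks, 1000, c(chr1 = 100000))
  expect_equal(start(bos) - 1, c(9000, 50000))
  expect_equal(end(bos), c(10000, 51000))
  expect_equal(mcols(bos)$side, c("5p", "3p"))
  # block starting at 0: only the downstream flank survives
  blocks0 <- transform(blocks, src_start = 0)
  bos0 <- defineBOS(blocks0, 1000, c(chr1 = 100000))
  expect_length(bos0, 1)
  expect_equal(mcols(bos0)$side, "3p")
})

test_that("every simulated breakpoint lies within 1 kb of an emitted BOS", {
  rea <- simulateRearrangement(5e6, 5, eventMix = c(translocation = 1),
                               minBlock = 100000, seed = 14)
  # express blocks with the derived genome as source (where BOS live)
  b <- mapBlocks(rea$map)
  inv <- data.frame(src_chrom = b$dst_chrom, src_start = b$dst_start,
                    src_end = b$dst_end, dst_chrom = b$src_chrom,
                    dst_start = b$src_start, dst_end = b$src_end,
                    strand = b$strand, score = 2e5)
  blocks <- elongateBlocks(CoordinateMap(inv), maxGap = 0)
  bos <- defineBOS(blocks, 1000, c(chr1 = 5e6))
  bosMid <- (start(bos) + end(bos)) / 2
  for (bp in rea$breakpoints)
    expect_true(min(abs(bosMid - bp)) <= 1000)
})

test_that("an identity map emits no interior BOS", {
  blocks <- elongateBlocks(identityMap(1e6), maxGap = 0)
  bos <- defineBOS(blocks, 1000, c(chr1 = 1e6))
  expect_length(bos, 0)  # both flanks clipped away at the chromosome ends
})

test_that("the duplication filter applies the inclusive 10% rule", {
  bos <- GRanges("chr1", IRanges(c(1, 1001, 2001, 3001), width = 1000))
  mcols(bos)$status <- "kept"
  hits <- list(c(1000, 910), c(1000), c(1000, 900), numeric())
  out <- duplicationFilter(bos, hits)
  expect_equal(mcols(out)$status,
               c("duplicated", "kept", "duplicated", "unmappable"))
  # strict variant keeps the exact-boundary case
  out2 <- duplicationFilter(bos, hits, inclusive = FALSE)
  expect_equal(mcols(out2)$status[3], "kept")
  # repeat mask removes overlapping kept BOS
  mask <- GRanges("chr1", IRanges(1500, 1600))
  out3 <- duplicationFilter(bos, hits, repeatMask = mask)
  expect_equal(mcols(out3)$status[2], "repeat_overlap")
})

gcTrack <- function(L = 1e6, win = 1000, hetero = TRUE, seed = 2) {
  set.seed(seed)
  n <- L / win
  v <- if (hetero) pmin(0.7, pmax(0.3, 0.45 +
         0.08 * as.numeric(stats::filter(rnorm(n), rep(0.2, 5),
                                         circular = TRUE)))) else rep(0.5, n)
  gr <- GRanges("chr1", IRanges(seq(1, L, by = win), width = win))
  mcols(gr)$score <- v
  gr
}

test_that("stratified sampling reproduces per-stratum counts exactly", {
  gc <- gcTrack()
  set.seed(3)
  st <- sort(sample(seq(0, 1e6 - 1000, by = 1000), 30))
  bos <- GRanges("chr1", IRanges(st + 1, st + 1000))
  sets <- gcStratifiedSample(bos, gc, nSets = 5, seed = 4)
  expect_length(sets, 5)
  for (s in sets) expect_length(s, 30)
  # per-stratum composition identical across sets
  comp <- lapply(sets, function(s) table(mcols(s)$stratum))
  for (k in 2:5) expect_equal(comp[[k]], comp[[1]])
})

test_that("sampled sets track the observed GC composition", {
  gc <- gcTrack()
  set.seed(8)
  # biased observed set: prefer high-GC windows
  gcv <- mcols(gc)$score
  pick <- sample(seq_along(gc), 40, prob = gcv^8)
  bos <- granges(gc[pick])
  obsGC <- mean(gcv[pick])
  means <- vapply(1:50, function(s) {
    sets <- gcStratifiedSample(bos, gc, nSets = 1, seed = s)
    mean(mcols(gc)$score[findOverlaps(sets[[1]], gc, select = "first")])
  }, numeric(1))
  expect_lt(abs(mean(means) - obsGC), 0.01)
  # and a uniform-GC genome reduces to uniform placement (no error)
  flat <- gcTrack(hetero = FALSE)
  expect_length(gcStratifiedSample(bos, flat, nSets = 1, seed = 1)[[1]], 40)
})

test_that("the BOS overlap Fisher test matches the enumeration oracle", {
  # equal overlap fractions: null result
  b <- GRanges("chr1", IRanges(c(1, 10001), width = 1000))
  bos <- GRanges("chr1", IRanges(c(1, 5001), width = 100))
  rnd <- list(GRanges("chr1", IRanges(c(1, 5001), width = 100)))
  res <- bosBoundaryOverlapTest(bos, b, rnd)
  expect_equal(res$log2_or, 0)
  expect_equal(res$p, 1)
  # [[3,1],[1,3]] table: p = 34/70 by full hypergeometric enumeration
  bos2 <- GRanges("chr1", IRanges(c(1, 2001, 4001, 50001), width = 100))
  bound <- GRanges("chr1", IRanges(1, 10000))
  rnd2 <- list(GRanges("chr1", IRanges(c(5001, 50001, 60001, 70001),
                                       width = 100)))
  res2 <- bosBoundaryOverlapTest(bos2, bound, rnd2)
  expect_equal(res2$p, oracleFisher(3, 1, 1, 3))
  expect_equal(res2$p, 34 / 70, tolerance = 1e-12)
  expect_error(bosBoundaryOverlapTest(bos2, bound, list()), "random")
})

test_that("boundaries planted at breakpoints enrich the BOS overlap test", {
  rea <- simulateRearrangement(2e7, 8, minBlock = 200000, seed = 21)
  b <- mapBlocks(rea$map)
  inv <- data.frame(src_chrom = b$dst_chrom, src_start = b$dst_start,
                    src_end = b$dst_end, dst_chrom = b$src_chrom,
                    dst_start = b$src_start, dst_end = b$src_end,
                    strand = b$strand, score = 2e5)
  blocks <- elongateBlocks(CoordinateMap(inv), maxGap = 0)
  bos <- defineBOS(blocks, 1000, c(chr1 = 2e7))
  # plant boundaries on every breakpoint plus background
  set.seed(22)
  bg <- sort(sample(seq(0, 2e7 - 1e4, by = 1e4), 50))
  bounds <- GRanges("chr1", IRanges(c(rea$breakpoints - 5000, bg + 1),
                                    width = 10000))
  gc <- GRanges("chr1", IRanges(seq(1, 2e7, by = 1000), width = 1000))
  mcols(gc)$score <- 0.41
  rnd <- gcStratifiedSample(bos, gc, nSets = 20, seed = 5)
  res <- bosBoundaryOverlapTest(bos, bounds, rnd)
  expect_lt(res$p, 0.05)
  expect_gt(res$log2_or, 0)
})

test_that("conservation permutation p-values handle ties and extremes", {
  pool <- rep(c("ultraconserved", "other", "human_specific"),
              c(100, 250, 50))
  # observed exceeding every permutation: p_over reported as 0 with note
  obs <- rep("human_specific", 30)
  res <- bosConservationPermutation(obs, pool, nPerm = 100, seed = 2)
  row <- res[res$category == "human_specific", ]
  expect_equal(row$observed, 30)
  expect_equal(row$p_over, 0)
  expect_match(row$note, "p < 1/100")
  # the (k+1)/(n+1) variant never reports zero
  res1 <- bosConservationPermutation(obs, pool, nPerm = 100, seed = 2,
                                     addOne = TRUE)
  expect_equal(min(res1$p_over), 1 / 101)
  # category absent from pool and observed: all permutations tie at 0
  pool2 <- rep(c("a", "b"), c(50, 50))
  res2 <- bosConservationPermutation(rep("a", 5), c(pool2, "c"),
                                     nPerm = 50, seed = 3)
  expect_equal(res2$p_over[res2$category == "c"], 1)
  # ties count on both sides
  expect_true(all(res2$p_over + res2$p_under >= 1))
  expect_error(bosConservationPermutation(character(), pool), "empty")
  expect_error(bosConservationPermutation(rep("a", 10), rep("a", 3)),
               "larger")
})
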
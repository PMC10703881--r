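# Independent brute-force oracles used across the suite. These deliberately
# re-derive every quantity from first principles (double loops, per-base
# maps, full enumeration) and share no code with the implementation.

library(GenomicRanges)

# diamond mean by explicit double loop; i is a 1-based bin, w in bins
oracleDiamondMean <- function(cts, i, w) {
  tot <- 0; n <- 0
  for (a in (i - w):(i - 1)) for (b in i:(i + w - 1)) {
    tot <- tot + cts[a, b]; n <- n + 1
  }
  tot / n
}

# expected simulated count for one cell by explicit boundary walk
oracleExpectedCount <- function(i, j, boundBins, strengths, A, alpha) {
  if (i == j) return(A)
  lo <- min(i, j); hi <- max(i, j)
  v <- A * (hi - lo)^(-alpha)
  for (k in seq_along(boundBins))
    if (boundBins[k] > lo && boundBins[k] <= hi) v <- v * strengths[k]
  v
}

# transitive-closure single-linkage clustering of intervals (0-based
# half-open starts/ends); gap measured end-to-start; returns cluster ids
oracleCluster <- function(starts, ends, gap) {
  n <- length(starts)
  id <- seq_len(n)
  repeat {
    changed <- FALSE
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (id[a] == id[b]) next
      g <- max(starts[a] - ends[b], starts[b] - ends[a])
      if (g <= gap) {
        id[id == id[b]] <- id[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(id, unique(id))
}

# per-base forward map through a block table (0-based src base -> dst base)
oracleMapBase <- function(blocks, base) {
  for (r in seq_len(nrow(blocks))) {
    if (base >= blocks$src_start[r] && base < blocks$src_end[r]) {
      off <- base - blocks$src_start[r]
      d <- if (blocks$strand[r] == "+") blocks$dst_start[r] + off
           else blocks$dst_end[r] - 1 - off
      return(list(chrom = blocks$dst_chrom[r], pos = d,
                  strand = blocks$strand[r]))
    }
  }
  NULL
}

# two-sided Fisher p for a 2x2 table by full hypergeometric enumeration
oracleFisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- vapply(support, function(x) dhyper(x, m, n, k), numeric(1))
  pObs <- dhyper(a, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

# two-sided exact binomial p by summing point masses <= observed mass
oracleBinom <- function(x, n, p) {
  probs <- dbinom(0:n, n, p)
  sum(probs[probs <= probs[x + 1] * (1 + 1e-7)])
}

# exhaustive synteny chaining: every maximal window of consecutive
# src-sorted blocks whose adjacent pairs are collinear, kept if it holds a
# seed; returns merged spans sorted by src
oracleChains <- function(blocks, minLen, minScore, maxGap) {
  b <- blocks[order(blocks$src_chrom, blocks$src_start), , drop = FALSE]
  n <- nrow(b)
  linkOK <- function(i, j) {
    if (b$src_chrom[i] != b$src_chrom[j]) return(FALSE)
    if (b$dst_chrom[i] != b$dst_chrom[j]) return(FALSE)
    if (b$strand[i] != b$strand[j]) return(FALSE)
    sg <- b$src_start[j] - b$src_end[i]
    dg <- if (b$strand[i] == "+") b$dst_start[j] - b$dst_end[i]
          else b$dst_start[i] - b$dst_end[j]
    sg >= 0 && sg <= maxGap && dg >= 0 && dg <= maxGap
  }
  seed <- (b$src_end - b$src_start) > minLen & b$score >= minScore
  out <- NULL
  i <- 1
  while (i <= n) {
    j <- i
    while (j < n && linkOK(j, j + 1)) j <- j + 1
    if (any(seed[i:j])) {
      mem <- b[i:j, , drop = FALSE]
      out <- rbind(out, data.frame(
        src_chrom = mem$src_chrom[1], src_start = min(mem$src_start),
        src_end = max(mem$src_end), dst_chrom = mem$dst_chrom[1],
        dst_start = min(mem$dst_start), dst_end = max(mem$dst_end),
        strand = mem$strand[1], score = max(mem$score)))
    }
    i <- j + 1
  }
  out
}

# small random interval set on one chromosome
randomIntervals <- function(n, L = 1e6, wmin = 100, wmax = 5000) {
  w <- sample(wmin:wmax, n, replace = TRUE)
  s <- sample.int(L - max(w), n, replace = TRUE)
  gr <- GRanges("chr1", IRanges(s, s + w - 1))
  mcols(gr)$name <- sprintf("iv%d", seq_len(n))
  mcols(gr)$score <- round(runif(n), 3)
  strand(gr) <- sample(c("+", "-", "*"), n, replace = TRUE)
  gr
}

# tiny labeled boundary pool shared by permutation-test checks
makeBoundaryPool <- function(n = 400, seed = 11) {
  set.seed(seed)
  pos <- sort(sample.int(5e7, n)) * 1
  gr <- GRanges("chr1", IRanges(pos, pos + 9999))
  mcols(gr)$score <- rnorm(n, -0.3, 0.5)
  mcols(gr)$geneOverlap <- runif(n) < 0.6
  gr
}
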
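#' @importFrom GenomicRanges GRanges mcols `mcols<-` reduce findOverlaps
#'   pintersect countOverlaps granges seqnames
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits DataFrame
NULL

# All interval I/O is BED-dialect: 0-based half-open on disk, converted to the
# 1-based closed GRanges convention in memory and back on write.

#' Read a BED file into a GRanges
#'
#' Reads BED3/BED6 (optionally with extra named columns, e.g. TE class and
#' family in columns 7-8) with strict validation: malformed lines are
#' rejected with their line number.
#'
#' @param path file path.
#' @param extraCols character vector naming columns beyond the sixth
#'   (e.g. `c("class", "family")` for TE BED6+2).
#' @return A `GRanges`; columns `name`, `score`, `strand` and any
#'   `extraCols` become metadata columns when present.
#' @export
readBed <- function(path, extraCols = character()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(GRanges())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(parts)
  if (any(ncol < 3L))
    stop(sprintf("BED line %d: fewer than 3 columns", lineno[which(ncol < 3L)[1]]),
         call. = FALSE)
  n <- min(ncol)
  mat <- t(vapply(parts, function(p) p[seq_len(n)], character(n)))
  if (n == 1L) mat <- t(mat)
  chromv <- mat[, 1]
  startv <- suppressWarnings(as.numeric(mat[, 2]))
  endv <- suppressWarnings(as.numeric(mat[, 3]))
  bad <- which(is.na(startv) | is.na(endv))
  if (length(bad))
    stop(sprintf("BED line %d: non-numeric start/end", lineno[bad[1]]),
         call. = FALSE)
  bad <- which(startv < 0 | startv >= endv)
  if (length(bad))
    stop(sprintf("BED line %d: requires 0 <= start < end", lineno[bad[1]]),
         call. = FALSE)
  bad <- which(!nzchar(chromv))
  if (length(bad))
    stop(sprintf("BED line %d: empty chrom", lineno[bad[1]]), call. = FALSE)
  gr <- GRanges(chromv, IRanges(startv + 1, endv))
  if (n >= 4L) mcols(gr)$name <- mat[, 4]
  if (n >= 5L) {
    sc <- suppressWarnings(as.numeric(mat[, 5]))
    mcols(gr)$score <- ifelse(mat[, 5] == ".", NA_real_, sc)
  }
  if (n >= 6L) {
    if (!all(mat[, 6] %in% c("+", "-", ".")))
      stop(sprintf("BED line %d: invalid strand",
                   lineno[which(!mat[, 6] %in% c("+", "-", "."))[1]]),
           call. = FALSE)
    GenomicRanges::strand(gr) <- sub("^\\.$", "*", mat[, 6])
  }
  if (length(extraCols) && n >= 6L + length(extraCols)) {
    for (k in seq_along(extraCols))
      mcols(gr)[[extraCols[k]]] <- mat[, 6L + k]
  }
  gr
}

#' Write a GRanges as BED
#'
#' @param gr a `GRanges`; `name`, `score` metadata and strand are written as
#'   BED columns 4-6 when present, further metadata columns named in
#'   `extraCols` as columns 7+.
#' @param path output path.
#' @param extraCols metadata columns to append after column 6.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path, extraCols = character()) {
  n <- length(gr)
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = start(gr) - 1, end = end(gr))
  mc <- mcols(gr)
  hasExtra <- length(extraCols) > 0
  if (!is.null(mc$name) || !is.null(mc$score) || hasExtra ||
      any(as.character(strand(gr)) != "*")) {
    df$name <- if (!is.null(mc$name)) as.character(mc$name) else "."
    df$score <- if (!is.null(mc$score)) ifelse(is.na(mc$score), ".",
                                               format(mc$score, trim = TRUE))
                else "."
    s <- as.character(strand(gr))
    df$strand <- ifelse(s == "*", ".", s)
    for (col in extraCols) df[[col]] <- as.character(mc[[col]])
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a bedGraph track
#'
#' @param path file path.
#' @return `readBedGraph`: a `GRanges` with a numeric `score` column.
#' @export
readBedGraph <- function(path) {
  gr <- readBed(path)
  tab <- read.table(path, sep = "\t", comment.char = "#",
                    colClasses = c("character", "numeric", "numeric", "numeric"))
  mcols(gr)$score <- tab[[4]]
  gr
}

#' @rdname readBedGraph
#' @param gr a `GRanges` with a `score` metadata column.
#' @export
writeBedGraph <- function(gr, path) {
  df <- data.frame(as.character(seqnames(gr)), start(gr) - 1, end(gr),
                   format(mcols(gr)$score, trim = TRUE))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write a contact matrix in COO text format
#'
#' The format has a 3-line header (`#chrom`, `#bin_size`, `#n_bins`) followed
#' by upper-triangle entries `bin_i TAB bin_j TAB count` with 0-based
#' `i <= j`. Unstated cells are zero. Duplicate `(i, j)` entries, `i > j`,
#' negative counts or bins outside the matrix are rejected with their line
#' number (duplicates are never silently summed).
#'
#' @param path file path.
#' @return `readMatrixCOO`: a [ContactMatrix-class].
#' @export
readMatrixCOO <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getHdr <- function(key) {
    m <- grep(paste0("^#", key, "\t"), hdr, value = TRUE)
    if (!length(m)) stop("COO header missing #", key, call. = FALSE)
    sub(paste0("^#", key, "\t"), "", m[1])
  }
  chromName <- getHdr("chrom")
  binSize <- as.integer(getHdr("bin_size"))
  nb <- as.integer(getHdr("n_bins"))
  body <- which(!grepl("^#", lines) & nzchar(lines))
  M <- matrix(0, nb, nb)
  if (length(body)) {
    parts <- strsplit(lines[body], "\t", fixed = TRUE)
    if (any(lengths(parts) != 3L))
      stop(sprintf("COO line %d: expected 3 columns",
                   body[which(lengths(parts) != 3L)[1]]), call. = FALSE)
    tab <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                  ncol = 3, byrow = TRUE)
    bad <- which(apply(is.na(tab), 1, any))
    if (length(bad))
      stop(sprintf("COO line %d: non-numeric field", body[bad[1]]),
           call. = FALSE)
    i <- tab[, 1]; j <- tab[, 2]; v <- tab[, 3]
    bad <- which(i > j)
    if (length(bad))
      stop(sprintf("COO line %d: requires bin_i <= bin_j", body[bad[1]]),
           call. = FALSE)
    bad <- which(v < 0)
    if (length(bad))
      stop(sprintf("COO line %d: negative count", body[bad[1]]), call. = FALSE)
    bad <- which(i < 0 | j >= nb)
    if (length(bad))
      stop(sprintf("COO line %d: bin outside [0, n_bins)", body[bad[1]]),
           call. = FALSE)
    key <- i * nb + j
    bad <- which(duplicated(key))
    if (length(bad))
      stop(sprintf("COO line %d: duplicate (bin_i, bin_j) entry", body[bad[1]]),
           call. = FALSE)
    M[cbind(i + 1, j + 1)] <- v
    M[cbind(j + 1, i + 1)] <- v
  }
  ContactMatrix(M, chrom = chromName, binSize = binSize)
}

#' @rdname readMatrixCOO
#' @param mat a [ContactMatrix-class].
#' @export
writeMatrixCOO <- function(mat, path) {
  cts <- counts(mat)
  nb <- nrow(cts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#chrom\t", chrom(mat)),
               paste0("#bin_size\t", binSize(mat)),
               paste0("#n_bins\t", nb)), con)
  ut <- which(upper.tri(cts, diag = TRUE) & cts != 0, arr.ind = TRUE)
  if (nrow(ut)) {
    ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]
    writeLines(sprintf("%d\t%d\t%s", ut[, 1] - 1L, ut[, 2] - 1L,
                       format(cts[ut], trim = TRUE, scientific = FALSE)), con)
  }
  invisible(path)
}

#' Read a UCSC chain file into a CoordinateMap
#'
#' Parses the standard chain dialect. The chain "target" genome becomes the
#' source and the "query" genome the destination. Negative-strand query
#' coordinates are converted to forward-strand 0-based half-open intervals;
#' the block `strand` records the reflection. Inconsistent block sums are
#' rejected.
#'
#' @param path chain file path.
#' @return A [CoordinateMap-class].
#' @export
readChain <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  out <- list()
  k <- 1L
  while (k <= length(lines)) {
    if (!nzchar(trimws(lines[k]))) { k <- k + 1L; next }
    f <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
    if (f[1] != "chain" || length(f) < 12L)
      stop("malformed chain header at line ", k, call. = FALSE)
    sc <- as.numeric(f[2])
    tName <- f[3]; tStart <- as.numeric(f[6]); tEnd <- as.numeric(f[7])
    qName <- f[8]; qSize <- as.numeric(f[9]); qStrand <- f[10]
    qStart <- as.numeric(f[11]); qEnd <- as.numeric(f[12])
    if (f[5] != "+") stop("chain target strand must be '+'", call. = FALSE)
    k <- k + 1L
    curT <- tStart; curQ <- qStart
    repeat {
      if (k > length(lines)) stop("truncated chain record", call. = FALSE)
      g <- strsplit(trimws(lines[k]), "[ \t]+")[[1]]
      size <- as.numeric(g[1])
      if (size > 0) {
        if (qStrand == "+") {
          ds <- curQ; de <- curQ + size; strd <- "+"
        } else {
          ds <- qSize - (curQ + size); de <- qSize - curQ; strd <- "-"
        }
        out[[length(out) + 1L]] <- data.frame(
          src_chrom = tName, src_start = curT, src_end = curT + size,
          dst_chrom = qName, dst_start = ds, dst_end = de,
          strand = strd, score = sc)
      }
      curT <- curT + size
      curQ <- curQ + size
      k <- k + 1L
      if (length(g) == 1L) break
      curT <- curT + as.numeric(g[2])
      curQ <- curQ + as.numeric(g[3])
    }
    if (curT != tEnd || curQ != qEnd)
      stop("chain block sums inconsistent with header span", call. = FALSE)
  }
  if (!length(out)) return(CoordinateMap(emptyBlockTable()))
  CoordinateMap(do.call(rbind, out))
}

#' Write a CoordinateMap as a UCSC chain file
#'
#' Each block is written as its own single-block chain record, which
#' round-trips through [readChain()]. Minus-strand blocks need the
#' destination chromosome sizes to recover strand-local coordinates.
#'
#' @param map a [CoordinateMap-class].
#' @param path output path.
#' @param dstSizes named numeric vector of destination chromosome sizes;
#'   required when any block is on the minus strand.
#' @export
writeChain <- function(map, path, dstSizes = NULL) {
  b <- mapBlocks(map)
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(b))) {
    x <- b[r, ]
    len <- x$src_end - x$src_start
    if (x$strand == "+") {
      qs <- x$dst_start; qe <- x$dst_end
      qsize <- if (!is.null(dstSizes) && x$dst_chrom %in% names(dstSizes))
        dstSizes[[x$dst_chrom]] else x$dst_end
    } else {
      if (is.null(dstSizes) || !x$dst_chrom %in% names(dstSizes))
        stop("dstSizes required for minus-strand blocks", call. = FALSE)
      qsize <- dstSizes[[x$dst_chrom]]
      qs <- qsize - x$dst_end; qe <- qsize - x$dst_start
    }
    srcsize <- if (!is.null(attr(map, "srcSizes"))) x$src_end else x$src_end
    writeLines(sprintf("chain %s %s %d + %d %d %s %d %s %d %d %d",
                       format(x$score, trim = TRUE, scientific = FALSE),
                       x$src_chrom, srcsize, x$src_start, x$src_end,
                       x$dst_chrom, qsize, x$strand, qs, qe, r), con)
    writeLines(c(as.character(len), ""), con)
  }
  invisible(path)
}

emptyBlockTable <- function() {
  data.frame(src_chrom = character(), src_start = numeric(),
             src_end = numeric(), dst_chrom = character(),
             dst_start = numeric(), dst_end = numeric(),
             strand = character(), score = numeric())
}
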
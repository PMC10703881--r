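.stars <- function(p) {
  ifelse(p < 0.0005, "***", ifelse(p < 0.005, "**",
         ifelse(p < 0.05, "*", "")))
}

#' Transposable-element enrichment at boundary CTCF sites
#'
#' CTCF peaks are assigned to boundary conservation groups by >= 1 bp
#' overlap with a labeled boundary. Each peak is labeled by the TE with the
#' largest overlap (ties broken by the earliest TE interval). For each TE
#' unit (class or family) in each group, the observed count of labeled
#' peaks is compared to the expectation
#' `nPeaksInGroup * (genomic bp covered by the unit / genomeSize)` with a
#' two-sided exact binomial test (pass a `dispersion` > 0 for an
#' overdispersed negative-binomial variant). Also reports, per group, the
#' fraction of boundaries with at least one CTCF site overlapping the unit.
#' No multiple-testing correction is applied by default (`adjust = "BH"`
#' enables it).
#'
#' @param boundaries labeled boundary `GRanges` (metadata column `label`).
#' @param ctcf CTCF peak `GRanges`.
#' @param te TE `GRanges` with `class` and `family` metadata columns.
#' @param genomeSize genome size in bp.
#' @param by `"family"` or `"class"`.
#' @param dispersion `NULL` for the exact binomial test, or a negative
#'   binomial size parameter for an overdispersed test.
#' @param adjust p-value adjustment method (`"none"` default).
#' @return data.frame per group x unit: `observed`, `expected`, `obs_exp`,
#'   `p`, `stars`, `boundary_frac` (fraction of group boundaries with a
#'   CTCF site overlapping the unit), `test`.
#' @export
teCtcfEnrichment <- function(boundaries, ctcf, te, genomeSize,
                             by = c("family", "class"), dispersion = NULL,
                             adjust = "none") {
  by <- match.arg(by)
  unitOf <- mcols(te)[[by]]
  labels <- mcols(boundaries)$label
  if (is.null(labels)) stop("boundaries need a 'label' column", call. = FALSE)
  # label each peak by its largest-overlap TE (ties -> earliest interval)
  hits <- findOverlaps(ctcf, te)
  peakUnit <- rep(NA_character_, length(ctcf))
  if (length(hits)) {
    ovw <- width(pintersect(ctcf[queryHits(hits)], te[subjectHits(hits)]))
    hdf <- data.frame(q = queryHits(hits), s = subjectHits(hits), w = ovw)
    hdf <- hdf[order(hdf$q, -hdf$w, hdf$s), ]
    hdf <- hdf[!duplicated(hdf$q), ]
    peakUnit[hdf$q] <- unitOf[hdf$s]
  }
  # unit genomic coverage (merged)
  units <- sort(unique(unitOf))
  cover <- vapply(units, function(u)
    sum(width(reduce(te[unitOf == u]))), numeric(1))
  res <- list()
  for (g in sort(unique(labels))) {
    bsel <- boundaries[labels == g]
    inG <- overlapsAny(ctcf, bsel)
    nPeaks <- sum(inG)
    if (!nPeaks) next
    for (ui in seq_along(units)) {
      u <- units[ui]
      obs <- sum(peakUnit[inG] == u, na.rm = TRUE)
      pr <- cover[ui] / genomeSize
      expd <- nPeaks * pr
      p <- if (is.null(dispersion)) {
        # as.numeric: binom.test returns a logical p at the degenerate p = 1
        as.numeric(stats::binom.test(obs, nPeaks, pr)$p.value)
      } else {
        # two-sided NB tail doubling around the same mean
        mu <- expd
        lo <- stats::pnbinom(obs, size = dispersion, mu = mu)
        hi <- stats::pnbinom(obs - 1, size = dispersion, mu = mu,
                             lower.tail = FALSE)
        min(1, 2 * min(lo, hi))
      }
      bWithUnit <- overlapsAny(bsel, IRanges::subsetByOverlaps(
        ctcf, te[unitOf == u]))
      res[[length(res) + 1L]] <- data.frame(
        group = g, unit = u, n_peaks = nPeaks, observed = obs,
        expected = expd, obs_exp = if (expd > 0) obs / expd else NA_real_,
        p = p, boundary_frac = mean(bWithUnit),
        test = if (is.null(dispersion)) "binomial" else "nbinom")
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) return(out)
  if (adjust != "none") out$p <- stats::p.adjust(out$p, method = adjust)
  out$stars <- .stars(out$p)
  rownames(out) <- NULL
  out
}

#' Chromatin-state fold enrichment at boundary groups
#'
#' `fold(state, group) = (bp of the state within group boundaries / total
#' group boundary bp) / (bp of the state genome-wide / genomeSize)`.
#' States absent genome-wide are reported as `NA`.
#'
#' @param states `GRanges` of state segments with a `state` metadata column
#'   (segments are expected to partition the annotated space).
#' @param boundaries labeled boundary `GRanges`.
#' @param genomeSize genome size in bp.
#' @return matrix of fold enrichments, states x groups.
#' @export
chromatinStateFoldEnrichment <- function(states, boundaries, genomeSize) {
  stateOf <- mcols(states)$state
  labels <- mcols(boundaries)$label
  stateNames <- sort(unique(stateOf))
  groups <- sort(unique(labels))
  genomeBp <- vapply(stateNames, function(s)
    sum(width(reduce(states[stateOf == s]))), numeric(1))
  out <- matrix(NA_real_, length(stateNames), length(groups),
                dimnames = list(stateNames, groups))
  for (g in groups) {
    b <- reduce(granges(boundaries[labels == g]))
    tot <- sum(width(b))
    if (!tot) next
    for (si in seq_along(stateNames)) {
      if (genomeBp[si] == 0) next
      seg <- states[stateOf == stateNames[si]]
      hits <- findOverlaps(seg, b)
      inB <- sum(width(pintersect(seg[queryHits(hits)], b[subjectHits(hits)])))
      out[si, g] <- (inB / tot) / (genomeBp[si] / genomeSize)
    }
  }
  out
}

#' CNV deletion recurrence at boundaries: case versus control
#'
#' A boundary counts as deleted in a cohort when at least one of that
#' cohort's deletion CNVs overlaps it by >= 1 bp. Over the same N
#' boundaries, builds the 2x2 table `[[deletedCase, notCase],
#' [deletedControl, notControl]]` and reports the two-sided Fisher's exact
#' test and odds ratio.
#'
#' @param boundaries `GRanges` of boundaries of one conservation group.
#' @param cnvCase,cnvControl deletion CNV `GRanges` per cohort.
#' @return one-row data.frame: `n`, `deleted_case`, `deleted_control`,
#'   `odds_ratio`, `p`, `stars`.
#' @export
cnvRecurrenceTest <- function(boundaries, cnvCase, cnvControl) {
  n <- length(boundaries)
  if (!n) stop("no boundaries supplied", call. = FALSE)
  delCase <- sum(overlapsAny(boundaries, cnvCase))
  delCtrl <- sum(overlapsAny(boundaries, cnvControl))
  tab <- matrix(c(delCase, n - delCase, delCtrl, n - delCtrl), 2,
                byrow = TRUE)
  ft <- stats::fisher.test(tab)
  data.frame(n = n, deleted_case = delCase, deleted_control = delCtrl,
             odds_ratio = unname(ft$estimate), p = ft$p.value,
             stars = .stars(ft$p.value))
}
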
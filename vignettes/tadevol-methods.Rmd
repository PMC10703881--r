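---
title: "Methods: cross-species TAD boundary conservation with tadevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species TAD boundary conservation with tadevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadevol)
```

# Scope and model

`tadevol` implements a comparative analysis of topologically associating
domain (TAD) boundaries across species: boundary calling from binned Hi-C
contact matrices via the insulation (TAD-separation) score, chain-based
liftover of boundaries to a reference genome, construction of a
union-boundary table and its evolutionary classification, detection of
evolutionary breaks of synteny (BOS) from pairwise alignment blocks, and the
statistics connecting boundary conservation to CTCF binding, transposable
elements (TEs), BOS and pathological copy-number variants (CNVs). A
synthetic multi-species generator supplies every input with exact ground
truth, so the whole pipeline can be validated end to end without external
data.

## Insulation score

For a symmetric contact matrix binned at `binSize` (10 kb throughout), the
diamond mean at bin $i$ for window $w$ (in bins) is the mean count over bin
pairs $(a, b)$ with $i - w \le a < i \le b < i + w$ — the $w \times w$ block
of contacts that pass across bin $i$. Windows run from `minDepth` (100 kb)
to `maxDepth` (600 kb) in 50 kb steps, giving 11 window sizes at 10 kb bins.
Per window, diamond means are `log1p`-transformed and standardized across
the chromosome (heavy-tailed counts make the log transform the stable
choice; bins whose window crosses the matrix edge are excluded from the
mean/sd estimation and reported as missing). The track score is the mean
z-score over windows; lower scores mean stronger insulation. The window
step (50 kb) is a package choice that brackets the min/max densely while
staying cheap.

## Boundary calling

Candidate boundaries are local minima of the score whose prominence — the
drop from the lower of the two flanking local maxima — is at least
`minDelta` (0.01). Significance is a one-sided Wilcoxon rank-sum test that
counts in the candidate's smallest-window diamond are lower than counts in
the two flanking diamonds centred at $i \pm w$. Those flanking diamonds are
distance-matched to the cross diamond (same distribution of pair distances)
and, for a true boundary, lie inside the neighbouring domains; comparing
against within-block triangles instead would be biased, because
cross-diamond pairs span systematically larger distances. P-values are
Benjamini–Hochberg corrected across candidates (`qThreshold` 0.05), and
calls closer than `minDepth` collapse to the lower-score one. The boundary
interval is the single 10 kb minimum bin. `minDelta` and the FDR threshold
stand in for unstated defaults of the field's standard callers and are
exposed as parameters.

## Liftover, union and classification

Liftover through a chain-derived `CoordinateMap` follows liftOver
semantics: an interval lifts iff at least `minMatch` (0.95, the
conventional threshold) of its bases map within a single destination
chromosome/strand run, and the output is the span of its mapped bases;
failures are reported, never dropped silently. The union table merges
lifted boundaries by single-linkage chaining with an end-to-start gap of at
most 10 kb (bedtools-merge semantics — chosen because "merged within 10 kb"
does not define transitivity; the test suite documents that chains can
exceed 10 kb end-to-end). Each source boundary joins exactly one chain.

Classification from presence/absence: *ultraconserved* = present in all
eight species; *primate-/rodent-conserved* = present in every member of one
clade and absent from the other (a looser at-least-two-members variant is
available via `strictOrderConservation = FALSE`); *human-/mouse-specific* =
present only in the clade's reference species and not within 10 kb of any
exclusion-set interval (mirroring the outgroup filter against chimpanzee
and gorilla boundary sets); everything else is *other*. Reference-species
group shares are reported with the reference-present row count as
denominator; union-row denominators differ and are reported separately
where relevant.

## Synteny blocks and BOS

Alignment blocks longer than 1 kb with score at least 100,000 seed synteny
blocks; seeds absorb neighbouring blocks of any size that are collinear
(same chromosomes and strand, consistent destination order, source and
destination gaps at most `maxGap`, default 1 Mb — the elongation gap
tolerance is otherwise unstated). BOS are the 1 kb flanks of each elongated
block, clipped at chromosome ends. Curation removes BOS whose second-best
re-mapping hit scores within 10% of the best (inclusive — a second hit at
exactly 90% of the top counts as duplicated; conservative, and flippable
via `inclusive = FALSE`), BOS with no hits, and optionally BOS overlapping
a repeat mask (mechanizing what would otherwise be manual curation of
segmental duplications). GC-stratified null sets draw, per GC-quantile
stratum of the observed BOS, the same number of 1 kb windows uniformly from
that stratum of the genome. Overlap with boundaries is tested two-sided by
Fisher's exact test on observed versus pooled random intervals, with a
Woolf 95% CI on the log2 odds ratio (0.5 continuity correction when a cell
is zero). The conservation-composition permutation test reports plain
proportions out of `nPerm` (default 100) as empirical one-tailed p-values,
with ties counted on both sides (so $p_{over} + p_{under} \ge 1$) and a
`(k+1)/(n+1)` variant behind `addOne = TRUE`; a zero proportion is flagged
with its resolution ("p < 1/nPerm").

## Enrichment statistics

TE enrichment at boundary CTCF sites labels each peak by its
largest-overlap TE (ties to the earliest interval) and compares observed
per-family (or per-class) counts in each conservation group against
`nPeaks * coverage/genomeSize` with a two-sided exact binomial test. The
binomial is the primary test; an overdispersed negative-binomial variant is
available through `dispersion` for sensitivity analysis. No
multiple-testing correction is applied by default (`adjust = "BH"` opts
in), and significance stars follow the 0.05/0.005/0.0005 convention.
Chromatin-state fold enrichment is pure coverage arithmetic. CNV recurrence
counts a boundary as deleted in a cohort when any of that cohort's deletion
CNVs overlaps it by at least 1 bp, over the same N boundaries in both
cohorts, and applies a two-sided Fisher test.

## Matched-insulation permutation

To separate insulation strength from gene content, the group statistic
(median insulation score) is compared against `nPerm` random boundary sets
matching the group's size *and* its number of gene-overlapping members,
drawn from all reference boundaries; $p = (1 + \#\{stat_{perm} \le
stat_{obs}\}) / (nPerm + 1)$, one-tailed towards stronger insulation.

# The synthetic generator

The generator defines the study conditions under which the pipeline is
validated:

* **Phylogeny.** A fixed rooted binary timetree of four primates (human,
  two gibbon genera, rhesus) and four rodents (mouse, two outgroup *Mus*
  species, rat), ultrametric at 80 My, with the gibbon split at 5 My and
  the *Mus* radiation at 3 My; shipped as a newick fixture.
* **Boundary turnover.** Root boundaries are lost along branches at
  `lossRate` per My and gained as a Poisson process at `gainRate` per bp
  per My, at uniform positions; lineage identifiers give exact n-way truth.
  Defaults (55 root boundaries, gain 8e-9/bp/My, loss 0.01/My on a 30 Mb
  chromosome) were tuned once so that roughly 15% of reference-species
  boundaries are ultraconserved and roughly 15% reference-specific, the
  broad structure reported for mammalian LCL/liver boundary surveys, and
  then frozen. Mouse-specific boundaries stay near 2%: with gains uniform
  in time, a 3 My terminal branch accrues few — a known divergence from the
  target that would require per-branch rates, which the uniform-gain design
  deliberately excludes.
* **Boundary spacing.** New positions keep at least `minSeparation`
  (150 kb) from every registered lineage position. This reflects observed
  mammalian TAD sizes (hundreds of kb) and keeps distinct lineages
  resolvable at the calling resolution; it also keeps the truth table
  exact under 10 kb union merging.
* **Contact matrices.** Expected counts follow $A (j-i)^{-\alpha}$ with
  $\alpha = 1$ and $A = 100$, attenuated by the product of strengths $s$ of
  boundaries strictly between the bins; planted strength is tied to true
  conservation, $s = 0.1 + 0.4 (8 - n_{way})/7$, so fully shared
  boundaries insulate strongly ($s = 0.1$) and single-taxon boundaries
  weakly ($s = 0.5$), reproducing the conserved-boundaries-insulate-more
  observation by construction. Poisson noise is optional and
  seed-deterministic.
* **Rearrangements.** Inversions and translocations applied to a collinear
  genome yield a bijective piecewise map with known junction breakpoints.
* **Annotations.** CTCF peaks at boundaries with probability 0.45 plus
  uniform background; TE families with uniform background and planted
  copies — an "old" family (MIR-like) at CTCF sites in ultraconserved
  boundaries and a "young" family (ERV-like) at reference-specific ones,
  with planting probability $1 - 1/odds$ so that odds 1 is exactly the
  null configuration; genes with extra mass at boundaries; a spatially
  smoothed GC field; iid-state chromatin segments; case/control deletion
  CNVs with per-boundary hit probabilities 0.30/0.14 at reference-specific
  boundaries plus background.

What the generator does **not** emulate: A/B compartments, loops, coverage
and mappability bias, sequence-level TE structure, tissue effects, and
non-uniform boundary placement. Passing tests therefore demonstrate
algorithmic correctness and statistical calibration under a clean planted
model, not performance on real Hi-C libraries.

# Numerical choices and degenerate inputs

* All interval I/O is BED-dialect, 0-based half-open on disk, 1-based in
  `GRanges` in memory; duplicate COO matrix entries are an error rather
  than summed, so generator bugs cannot hide behind silent aggregation.
* Constant-score windows (zero sd) give z = 0 rather than NaN; constant GC
  tracks collapse stratified sampling to uniform placement.
* Matrices shorter than twice `maxDepth` produce an all-missing track with
  a warning; empty tracks produce empty call sets; zero usable pileup
  anchors are an error.
* All randomness flows from one master seed through named substreams
  (`substreamSeed`), so every stage is reproducible independently and the
  end-to-end demo is byte-identical across runs with one seed.

# Validation design and problem sizes

The test suite checks every operation against independent oracles:
brute-force double loops for diamond means (matrices up to 100 bins),
per-base mapping for liftover and chain parsing, transitive-closure
clustering for union merging, exhaustive collinear-chain enumeration for
synteny blocks (up to 60 blocks), and full hypergeometric/binomial
enumeration for the exact tests. Planted-structure recovery uses a 2 Mb
chromosome with 20 boundaries of strength 0.2 under Poisson noise (windows
50–250 kb, matched to that chromosome's scale), and the end-to-end
demonstration uses the default 30 Mb eight-taxon simulation, with label
recovery assessed over boundaries inside the scorable extent (insulation is
undefined within `maxDepth` of the chromosome ends). Null calibration runs
200 replicates per test, with designs chosen to keep the discrete
permutation distributions fine-grained (balanced two-category pools;
point-like CTCF summits so that the binomial coverage model holds exactly).
These sizes are the package's validation conditions; they run comfortably
on a laptop.

# Known limitations

* The liftover treats one destination chrom/strand run per interval; split
  boundaries (straddling a rearrangement) fail rather than partially lift,
  which matches the conservative filtering the classification relies on.
* Group shares depend on the denominator convention; both
  reference-present and union-row denominators are computable, and the
  reported functions state which they use.
* The empirical permutation p out of `nPerm` can be exactly zero; it is
  reported with its resolution rather than clamped.
* The generator's mouse-specific share (see above) and its lack of real
  Hi-C artefacts limit how far calibration results transfer to real data.

# Pipeline interface

`runConfig()` collects every stage parameter with defaults; values can be
loaded from a YAML file and are validated before any stage runs.
`runStage()` drives single stages over the documented plain-text formats
(BED/bedGraph, COO matrix text, UCSC chain, TSV), and `runDemo()` runs the
full synthetic demonstration from one seed, writing every artifact plus a
JSON manifest and a truth-comparison report. In R, the exported functions
are the primary interface:

```{r demo, eval = FALSE}
cfg <- runConfig(seed = 1)
res <- runDemo(seed = 1, outDir = "demo_out", config = cfg)
res$recovery$perLabel
```
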
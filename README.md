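# tadevol

Cross-species analysis of TAD boundary evolutionary conservation.

Topologically associating domains (TADs) partition mammalian genomes into
self-interacting units whose boundaries — typically CTCF-bound insulator
elements — constrain enhancer–promoter contacts. How stable those
boundaries are over evolutionary time, and what distinguishes deeply
conserved boundaries from recently gained ones, is a central question in
comparative regulatory genomics. `tadevol` provides, in one R package, the
full analysis chain needed to answer it from binned Hi-C matrices and
pairwise genome alignments:

* **Insulation and boundary calling.** The TAD-separation score of bin *i*
  is the mean over window sizes *w* (100–600 kb) of the per-chromosome
  z-score of `log1p` diamond means *d(i, w)* — the mean contact count over
  bin pairs *(a, b)* with *i−w ≤ a < i ≤ b < i+w*. Boundaries are
  statistically significant local minima of the score (prominence filter,
  one-sided rank-sum test against distance-matched flanking diamonds,
  Benjamini–Hochberg FDR).
* **Conservation classification.** Boundaries from each species are lifted
  to a reference genome through alignment chains (liftOver semantics,
  minMatch 0.95), merged within 10 kb into a union-boundary table, and
  labeled from their presence/absence pattern: ultraconserved (all
  species), primate-/rodent-conserved (one clade only), human-/mouse-
  specific (reference species only, after outgroup exclusion), or other.
* **Breaks of synteny (BOS).** Alignment blocks > 1 kb with score ≥ 100,000
  seed greedy collinear chaining into synteny blocks; BOS are their 1 kb
  flanks, curated by a second-best-hit-within-10% duplication filter and an
  optional repeat mask, and tested against boundaries with GC-stratified
  random sets (Fisher's exact test, log2 odds ratio with Woolf CI) and
  one-tailed permutation tests of conservation-group composition.
* **Enrichment statistics.** Transposable-element classes/families at
  boundary CTCF sites (exact binomial against genomic coverage),
  chromatin-state fold enrichment, CNV deletion recurrence in case versus
  control cohorts (Fisher), and a gene-overlap-matched insulation
  permutation test.
* **Synthetic multi-species generator.** Boundary gain/loss on a fixed
  eight-taxon phylogeny (four primates, four rodents, 80 My deep) with
  lineage-tracked ground truth, contact matrices with planted insulation,
  rearranged genomes with known breakpoints, and annotation tracks (CTCF,
  TEs, genes, GC, chromatin states, CNVs) with controllable planted
  effects — so every stage is testable end to end offline.

## Worked example

Simulate the eight-taxon study, call boundaries in the human matrix, and
run the full demonstration:

```r
library(tadevol)

phylo <- defaultPhylogeny()
sim <- simulateBoundaryEvolution(phylo, evolutionParams(), seed = 1)
table(sim$truth$label)
#>    human_specific    mouse_specific             other primate_conserved
#>                 2                 1                39                12
#>  rodent_conserved    ultraconserved
#>                19                 9

cm <- simulateContactMatrix(sim$boundaries$human, 3e7,
                            seed = substreamSeed(1, "human"))
tr <- insulationTrack(cm)    # 11 window sizes, 100-600 kb
calls <- callBoundaries(tr, cm)
head(calls, 3)
#> GRanges object with 3 ranges and 4 metadata columns:
#>       seqnames          ranges strand |     score     delta      pvalue      qvalue
#>   [1]     chr1 1850001-1860000      * |  -2.43361   1.84553 6.32419e-30 1.15021e-28
#>   [2]     chr1 2140001-2150000      * |  -2.48826   1.74394 1.18695e-26 1.38161e-25
#>   [3]     chr1 2470001-2480000      * |  -1.72795   1.33884 8.47662e-19 7.70843e-18
```

Each call is one 10 kb bin: `score` is the insulation minimum (lower =
stronger insulation), `delta` its prominence, and `qvalue` the FDR-adjusted
rank-sum significance of the contact depletion across the bin.

The end-to-end demo chains simulation → matrices → insulation → calling →
liftover → union → classification → annotation statistics → BOS detection,
writes every artifact plus a JSON manifest, and compares recovered labels
to the simulated truth:

```r
res <- runDemo(seed = 1, outDir = "demo_out")
round(res$recovery$perLabel, 3)
#>             other primate_conserved    ultraconserved  rodent_conserved
#>                 1                 1                 1                 1
#>    human_specific    mouse_specific
#>                 1                 1
res$groupSummary$summary[, c("label", "n", "median_score")]
#>               label  n median_score
#> 1    human_specific  2    -1.341108
#> 2             other 13    -2.764120
#> 3 primate_conserved 12    -2.410648
#> 4    ultraconserved  8    -4.517898
```

Every true conservation label is recovered at this seed, and the group
summary shows the planted structure the statistics are designed to detect:
ultraconserved boundaries have the most negative (strongest) insulation,
species-specific ones the weakest.

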
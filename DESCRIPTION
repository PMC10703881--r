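Package: tadevol
Title: Cross-Species TAD Boundary Conservation and Synteny Breakpoint Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative analysis of topologically associating domain (TAD)
    boundaries across species. Computes insulation (TAD-separation) scores
    from binned Hi-C contact matrices, calls boundaries as significant local
    minima, lifts boundaries between genomes through alignment chains, builds
    a reference union-boundary map and classifies boundaries by evolutionary
    conservation (ultraconserved, order-conserved, species-specific). Detects
    evolutionary breaks of synteny (BOS) from pairwise alignment blocks and
    tests their association with boundary conservation groups using
    GC-stratified null models, Fisher's exact and permutation tests.
    Annotation enrichment statistics cover transposable-element families at
    boundary CTCF sites, chromatin-state fold enrichment and pathological CNV
    recurrence. Ships a multi-species synthetic data generator (boundary
    gain/loss on a phylogeny, contact matrices with planted insulation,
    rearranged genomes with known breakpoints) so the full pipeline is
    testable end-to-end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    ape,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
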
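Package: pairseg
Title: Pairwise Comparison and Segmentation of Near-Identical Bacterial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-genome comparison of pairs of closely related bacterial
    chromosomes. Decomposes near-identical genome pairs into exactly identical
    runs and divergent connectors and types the differences (point mutations,
    one-base indels, tandem-repeat copy-number changes, inversions, long
    indels); segments moderately diverged pairs into matching segments
    (matchSEGs) and divergent segments (divSEGs) with a three-pass
    alignment-based procedure; computes match/mismatch/gap-open/gap-extension
    column statistics and the (mm + go) / (m + mm + go) divergence measure;
    builds per-base position-correlation maps; classifies divergent segments
    as indels, approximate inserts, replacements or tandem copy-number
    variations; correlates protein-coding genes between two annotated genomes
    with start-codon reconciliation and derives strain-specific and disrupted
    gene sets; and provides gene-level diagnostics (CDS mutation typing,
    rRNA operon comparison, mobile-element census and consensus, in-silico
    PCR). A synthetic genome-pair generator with exhaustive ground-truth
    tables makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
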
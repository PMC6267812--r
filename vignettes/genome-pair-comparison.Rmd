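---
title: "Comparing near-identical bacterial genome pairs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing near-identical bacterial genome pairs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairseg)
```

## The problem

Two genome sequences of the same bacterial strain — or of two strains assumed
to be parent and derivative — can be compared at two very different levels of
divergence, and the appropriate method differs:

* **Near-identical pairs** (two assemblies of the same strain; a clone and
  its presumed ancestor) differ at a handful of positions. Here an
  *exact-match* decomposition is both the fastest and the most interpretable
  description: the two sequences split into an alternating series of **runs**
  (maximal stretches of complete identity) and **connectors** (the divergent
  material between runs), and each connector is one difference event.
* **Moderately diverged pairs** (independent isolates of one subspecies, say
  99–99.9% identical with strain-specific islands) need an alignment-based
  description: the chromosomes toggle between **matchSEGs** — colinear,
  low-divergence matching segments — and **divSEGs** — indels, inserts,
  replacements and tandem-repeat expansions between them.

`pairseg` implements both, plus the derived analyses a genome-comparison
study actually reports: per-base position-correlation maps, divSEG
categorisation, ortholog (ORF) correlation between two annotated genomes,
disrupted- and strain-specific-gene sets, CDS mutation typing, rRNA operon
comparison, a mobile-element census and in-silico PCR strain diagnostics.
A synthetic genome-pair generator with an exhaustive ground-truth table makes
every stage testable at desk scale without downloads.

## The exact-match mapper

`decompose(a, b, min_run)` anchors on k-mers (k = `min_run`, default 20 bp)
that occur exactly once in each genome, chains the shared anchors colinearly
(longest strictly increasing subsequence, ties resolved leftmost in genome
a), merges same-diagonal anchors, extends every anchor region to its maximal
exact match, trims overlaps between consecutive runs, and finally recovers
boundary matches at the sequence ends whose k-mers were non-unique. The
result is an alternating run/connector partition whose concatenation
reconstructs both inputs byte-exactly — an invariant checked by
`check_reconstruction()` and asserted across the test suite.

`type_differences()` assigns one record per connector (after the complex-
event checks): equal-length 1↔1 → point mutation; 0↔1 → one-base indel;
reverse-complement sides → inversion; extra material that is a whole number
of 7–16 bp tandem units present in the flanks of both genomes → copy-number
variation; one empty side longer than 50 bp → long indel; short two-sided
connectors → few-base difference. The 50 bp boundary and the internal
handling of inversions and tandem units (in place of an external
similarity-search step) are package design choices.

**min_run = 20** suppresses chance micro-matches inside connectors (a random
20-mer recurs in a 5 Mb genome with probability ≪ 1) while leaving 1-base
events resolvable. Two caveats follow from the anchoring strategy: exact
matches shorter than `min_run`, and matches whose every k-mer recurs
elsewhere (e.g. inside long tandem arrays), are absorbed into connectors —
which is exactly where the tandem copy-number logic expects them.

### Coordinates

All internal coordinates are 0-based half-open on the forward strand;
conversion to 1-based inclusive happens only when writing GenBank or GFF3.
Circular chromosomes are handled linearised at their given origin; the
comparison does not wrap across the origin, so a pair of circular genomes
should be opened at equivalent ring positions before comparison. `N` bases
are kept and always count as mismatches.

## The three-pass segmentation

`compare_genomes()` runs three passes:

1. **Chunked traversal** (`first_pass`). The genomes are compared in chunks
   of 200 kb (configurable). Each chunk is decomposed into runs and
   connectors; connectors are aligned; the alignment up to the beginning of
   the last matching stretch is emitted, and the next chunk restarts at that
   stretch, so insertions cannot desynchronise the traversal. When the last
   matching stretch would give less than a quarter-chunk of progress — a
   fully identical chunk with a divergent tail is the degenerate case — the
   restart point moves to 200 bp before the end of that stretch instead.
   This guarantees termination while restarting, as intended, at the
   beginning of a matching stretch.
2. **Segment extraction** (`extract_segments`). The emitted chunk alignments
   concatenate into one genome-wide alignment. matchSEGs end wherever an
   indel longer than 100 bp occurs, or where a sliding window of 1000
   informative alignment columns (match, mismatch, gap-open; gap-extension
   columns carry no information and are skipped) exceeds 5% divergence.
   Every matchSEG is trimmed so its first and last column is an identical
   base pair; everything between matchSEGs is a divSEG.
3. **Refinement** (`refine`). matchSEGs containing internal indels > 100 bp
   are split; matchSEGs separated by less than 100 bp *in both genomes* are
   fused, the fused span re-aligned and its statistics recomputed; the
   passes iterate to a fixed point (`refine()` is idempotent). matchSEGs
   above 1% divergence are *retained but flagged* for review — a
   configurable report, not an automatic conversion into divSEGs.

The **5% / 1 kb window rule** replaces a manual visual-inspection step with
a stated, testable criterion; segment counts on real data are therefore
reproducible but may differ slightly from counts produced with manual
curation. The partition invariant — every position of each genome belongs to
exactly one segment — is enforced programmatically after refinement.

### The alignment engine

Small problems (up to 10^7 DP cells) are aligned with the affine-gap
Needleman–Wunsch of `Biostrings::pairwiseAlignment()` (match +1, mismatch
−2, gap open 4, gap extension 1; a gap of length L costs 4 + L). Larger
near-identical problems are anchored on the run/connector decomposition, and
only the connectors are aligned by DP; two-sided connectors beyond the DP
budget are emitted as two adjacent gap blocks, which is the correct
segmentation outcome for a long replacement (it exceeds the 100 bp indel
rule either way). Alignment is deterministic for fixed inputs; equal-score
tie-breaking follows the DP engine's traceback order rather than an explicit
left-shift-in-a rule — determinism, the purpose of a tie-break, is preserved.

## Column statistics and divergence

Every alignment column is exactly one of match (`m`), mismatch (`mm`),
gap open (`go`) or gap extension (`ge`); the first column of each maximal
gap run in either row is its single `go`. Sequence divergence is

$$\mathrm{div} = \frac{mm + go}{m + mm + go},$$

with gap-extension columns excluded throughout, so a 1-base indel and a
500 bp indel each contribute a single difference event. Genome-wide
statistics are computed by summing the four counts across matchSEGs and
applying the formula once — cumulative identity, never an average of
per-segment fractions.

The **position-correlation map** classifies every base of each genome as
`mapped` (within a matchSEG and aligned to a partner base, whose coordinate
is recorded), `gap` (within a matchSEG, opposite an alignment gap) or
`strain_specific` (within a divSEG). The mapped relation is a strictly
increasing partial bijection and doubles as a coordinate liftover table.

## divSEG categories

Each divSEG receives exactly one category, tested in this order:

1. **tandem_cnv** — the extra material is tandem copies of a 7–16 bp unit
   (the two stated unit ranges for this class of repeat are merged to one
   7–16 bp band) present in the flanks of both genomes; the full copy
   numbers on both sides are counted by extending through the flanking
   array. Unit detection accepts up to 10% mismatching positions and
   requires the tiling to explain at least 90% of the sequence — tolerance
   values chosen here, since no published figure exists for them.
2. **indel** — exactly one side empty: the insert is positioned at an exact
   point.
3. **approximate_insert** — up to 10 unaligned bases on the other side.
4. **replacement** — dissimilar sequence on both sides; homology is reported
   as global-alignment identity, and segments at ≥ 95% identity are tagged
   as candidates for matchSEG status rather than silently reclassified.

Inserts that occur at ≥ 90% identity over ≥ 80% of their length elsewhere in
their own genome are tagged `InternallyRepeated` (seed-and-verify search:
exact 16-mer seeds followed by alignment verification of candidate loci).

## ORF correlation

Protein-coding genes are paired through the position map: C-terminal
positions first (the terminus coordinate must map *exactly*, 0 bp slack, to
the partner gene's terminus on the same strand), then N-terminal positions
for the remainder; a correlation requires at least one terminus inside a
matchSEG. A pair is **perfect** when both termini map to equivalent
positions, lie in the same matchSEG, and the product names are identical.
Genes wholly inside divSEGs are **strain_specific**; the rest are
**unmapped**.

Protein identity of a pair is verified with start-codon reconciliation: for
inconsistent starts the C-terminal fragments must be identical for the
length of the shorter ORF, converting the longer protein's internal Val/Leu
to Met when the shorter ORF's annotated start codon is GTG/TTG.

**Disrupted genes** are found structurally: a regular gene whose mapped span
in the partner genome contains a pseudo-flagged CDS, or a set of two or
three ORFs (a split gene — the typical frameshift signature), is reported as
a disrupted pair; pairs pseudo-flagged on both sides are excluded.

**Strain-specific gene lists** drop candidates with a close homolog (best
cross-proteome global-alignment identity ≥ 75%, computed after a shared
5-mer prescreen) and candidates whose product name matches a configurable
mobile-element/phage keyword list (defaults: transposase, integrase, phage,
prophage). Candidates shorter than 150 nt with no cross-proteome hit at all
are re-rated `spurious_candidate`; database lookups are out of scope, so
this length-plus-no-hit rule deliberately approximates a curation step that
is manual in practice. One observed consequence worth knowing: genes inside
a long inversion fall into a divSEG (the segmentation is colinear), enter
the strain-specific candidate list of both genomes, and are then correctly
removed by the homolog filter — the filter, not the segmentation, is what
rescues inverted-but-conserved genes.

## Gene-level diagnostics

* `compare_cds()` compares two equal-length in-frame CDSs codon by codon
  (bacterial genetic code, table 11). Each differing base is one point
  mutation; bases in codons whose amino acid changes are non-silent, and
  replacements are labelled `<refAA><pos><altAA>` with 1-based residue
  numbering on the genome-a protein (so the classic rifampicin-resistance
  positions read as, e.g., H526Y).
* `compare_rrna_sets()` pairs rRNA operons through the position map and
  reports per-pair base differences from a global alignment.
* `mite_census()` finds all non-overlapping copies of an element consensus
  on both strands; a copy is *complete* at ≥ 90% of the consensus length and
  ≥ 80% identity (census thresholds chosen here and recorded so the census
  is reproducible), and flanking TA target-site duplications are recorded.
  `consensus_from_copies()` builds the per-column majority consensus (ties
  broken A < C < G < T) plus the base-frequency matrix for logo rendering.
* `insilico_pcr()` places the forward primer and the reverse primer's
  reverse complement on the plus strand (and the mirrored orientation) and
  reports every product up to 5000 bp; the product length is the inclusive
  span from the forward primer's 5' base to the reverse primer's 3' base.
  Primer matching defaults to 0 mismatches, configurable to ≤ 3 with the
  3'-terminal base always required to match — mimicking PCR specificity.

## The synthetic genome-pair generator

`mutation_spec()` → `generate_ancestor()` → `mutate_pair()` produce two
descendants of a random ancestor plus a truth table recording every event's
type, carrier genome, ancestor and derived coordinates, and payload.

What it emulates, and the default study conditions:

* a ~200 kb circular chromosome at 43% GC (the GC content typical of the
  enteric entomopathogens this kind of comparison targets), with a planted
  gene grid (one ~900 bp CDS per 1.5 kb; start codons ATG/GTG/TTG in
  0.80/0.14/0.06 proportions; no internal stops; an in-frame internal ATG at
  60% of each gene so frameshift splits always leave a translatable
  C-terminal ORF);
* 200 point mutations, 12 intergenic 1-base indels, 4 CDS frameshifts,
  4 mobile-element insertions (a fixed synthetic 123 bp MITE-like element
  with 25 bp terminal inverted repeats, inserted at TA sites with a TA
  target-site duplication), 1 inversion of 2–5 kb bounded by planted 40 bp
  inverted repeats, 2 tandem-repeat copy-number changes (7–12 bp units,
  10–15 ancestral copies, 15–25 extra copies in the carrier) and 3
  prophage-like strain-specific blocks of 1–8 kb carrying 5 unique and 2
  near-duplicate genes. Observed inter-strain event densities are roughly
  2300 point mutations and 60 frameshifts per Mb; with the 200 bp spacing
  guarantee below, that point-mutation density is not packable, so the
  default emulates about half of it (1 per kb) — the structure, not the
  saturation, of real divergence.

Design guarantees that make truth recovery exact rather than merely likely:

* **200 bp spacing** between event footprints, so every event falls into its
  own connector/divSEG;
* 1-base indels avoid homopolymer-ambiguous placements (the inserted or
  deleted base differs from both neighbours);
* strain-specific block payloads have pinned edge bases (differing from
  their flanks), so flanking exact matches cannot slide into the insert;
* frameshift placements are simulated before acceptance and retried until
  the premature stop and a downstream in-frame start produce a clean
  two-ORF split, emitted *without* pseudo flags so disruption must be
  inferred, not read off the annotation;
* near-duplicate genes never take a frameshifted gene as their source.

Two recovered-coordinate conventions are inherent to the biology rather than
limitations: an element inserted with a TA target-site duplication is
ambiguous in placement by the duplicated bases (recovered breakpoints may
shift by ±2 bp), and an inversion bounded by inverted repeats is detected as
its *core* — the repeats themselves remain identical in both genomes, so the
recovered inverted interval is the truth interval minus one repeat length at
each end.

What the generator does **not** emulate: substitution-rate heterogeneity and
transition/transversion bias, selection on genes, repeat families beyond the
single planted element, rearrangements other than single inversions, and
assembly artefacts. Passing the recovery tests therefore demonstrates the
pipeline's correctness on isolated, well-spaced events — not its behaviour
on saturated divergence, nested events or repeat-rich real chromosomes,
where the flagged-segment review and the approximate-insert tolerance do the
corresponding work.

Randomness comes from R's Mersenne–Twister via `set.seed()` — a named,
portable generator — and the seed is recorded in every emitted fixture
header.

## Numerical choices and degenerate inputs

* Alignment scoring: match +1, mismatch −2, gap open 4, gap extension 1;
  DP cell budget 10^7 before anchoring takes over.
* `divergence()` errors on all-gap-extension input rather than returning a
  silent NaN; `classify_columns()` rejects columns gapped in both rows.
* Sequences with no common run of `min_run` bases decompose into a single
  whole-genome connector — a result, not an error.
* Consensus ties break by the fixed base order A < C < G < T; tandem-unit
  detection returns the *smallest* qualifying unit length.
* Identity comparisons are exact limits: one matchSEG, zero divSEGs,
  divergence 0, identity position bijection.

## Problem sizes

The shipped analyses and tests run at desk scale: 200 kb default pairs for
the segmentation workflow, a 500 kb pair for the exact-match mapper, 4–16 kb
pairs for the randomized partition checks, and 30–150 kb constructions for
targeted recovery tests. The same code paths run at full chromosome scale
(5–6 Mb) through the anchored alignment route; `analysis/07` documents the
full-scale reproduction workflow, which requires a one-off download of the
three published chromosomes it compares.

## Known limitations

* The comparison assumes colinear genomes; rearrangements beyond single
  inversions (translocations, multi-segment shuffles) are out of scope and
  will surface as replacements or long indels.
* Exact matches shorter than `min_run` are not anchored; connectors can
  therefore contain short identical stretches, which the difference typing
  accounts for but the run list does not show.
* The window rule that terminates high-divergence matchSEGs is a stated
  replacement for manual curation; headline segment counts on real data can
  shift slightly relative to manually curated analyses.
* ORF-correlation statuses other than `perfect` approximate a curation
  process that is partly manual in published practice; counts derived from
  keyword filters alone will not reproduce manually curated lists exactly.
* Circular origins are not wrapped; events spanning the ring-opening point
  of a circular chromosome must be handled by re-opening the sequences at
  equivalent positions first.
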
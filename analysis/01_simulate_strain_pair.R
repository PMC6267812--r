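#!/usr/bin/env Rscript
# Step 1 — simulate the study's strain pair.
#
# Generates a pair of ~200 kb circular chromosomes that differ the way two
# closely related bacterial isolates do: point mutations, 1-base indels
# (some disrupting genes), mobile-element insertions with TA target-site
# duplications, a bounded inversion, tandem-repeat copy-number changes and
# prophage-like strain-specific blocks carrying strain-specific genes.
# Writes the FASTA/GenBank fixtures and the ground-truth table under
# results/fixtures/.

library(pairseg)

spec <- mutation_spec(seed = 20260926L)
pair <- generate_pair(spec)
print(pair)

paths <- emit_fixture(pair, "results/fixtures")
write_report(pair$planted_genes, "results/fixtures/planted_genes.tsv", "tsv")

cat("\nEvent classes seeded:\n")
print(table(pair$truth$type))
cat("\nWrote:", paste(basename(paths), collapse = ", "),
    "and planted_genes.tsv to results/fixtures/\n")
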
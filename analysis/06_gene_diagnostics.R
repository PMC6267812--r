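#!/usr/bin/env Rscript
# Step 6 — gene-level diagnostics.
#
# Four analyses on the simulated pair:
#   (a) point-mutation typing of a resistance-style CDS (silent vs
#       non-silent, amino-acid replacement labels);
#   (b) position-correlated comparison of planted rRNA operons;
#   (c) census and consensus of the mobile element, with TA target-site
#       duplications and a length histogram;
#   (d) in-silico PCR with primer pairs that straddle a strain-specific
#       block, so the product length differs diagnostically between strains.
# Writes cds_comparison.txt, rrna_pairs.tsv, mite_census.tsv,
# mite_consensus.txt and pcr_products.tsv under results/.

library(pairseg)

## (a) CDS mutation typing: seed 9 point mutations into one gene ------------
set.seed(20260926)
nt <- paste0("ATG", paste(sample(setdiff(
  names(Biostrings::getGeneticCode("11")), c("TAA", "TAG", "TGA")),
  1098, replace = TRUE), collapse = ""), "TAA")
mut <- nt
for (cp in c(12, 101, 205, 333, 414, 752, 901)) {   # 7 silent (Leu CTG->CTA)
  substr(nt, cp * 3 - 2, cp * 3) <- "CTG"
  substr(mut, cp * 3 - 2, cp * 3) <- "CTA"
}
substr(nt, 526 * 3 - 2, 526 * 3) <- "CAC"           # His526 -> Tyr
substr(mut, 526 * 3 - 2, 526 * 3) <- "TAC"
substr(nt, 995 * 3 - 2, 995 * 3) <- "GAA"           # Glu995 -> Gly
substr(mut, 995 * 3 - 2, 995 * 3) <- "GGA"
cc <- compare_cds(nt, mut)
print(cc)
dir.create("results", showWarnings = FALSE)
writeLines(c(sprintf("point_mutations\t%d", cc$n_point_mutations),
             sprintf("silent\t%d", cc$n_silent),
             sprintf("nonsilent\t%d", cc$n_nonsilent),
             sprintf("replacements\t%s", paste(cc$aa_replacements, collapse = ","))),
           "results/cds_comparison.txt")

## (b) rRNA operon comparison ------------------------------------------------
spec_r <- mutation_spec(genome_length = 80000L, n_snp = 20L, n_1bp_indel = 0L,
                        n_frameshift = 0L, n_inversion = 0L, n_tandem_cnv = 0L,
                        n_mge_insertion = 0L, n_block_indel = 0L,
                        n_unique_genes = 0L, n_dup_genes = 0L,
                        n_rrna = 7L, seed = 20260927L)
pair_r <- generate_pair(spec_r)
pm_r <- build_position_map(compare_genomes(pair_r$a, pair_r$b))
rr <- compare_rrna_sets(pair_r$a, pair_r$b, pm_r)
write_report(rr$pairs, "results/rrna_pairs.tsv", "tsv")
cat(sprintf("\nrRNA operons paired: %d; identical: %d; differing: %d\n",
            nrow(rr$pairs), sum(rr$pairs$n_differences == 0),
            sum(rr$pairs$n_differences > 0)))

## (c) mobile-element census --------------------------------------------------
a <- read_genome("results/fixtures/a.gbk", "genbank")
b <- read_genome("results/fixtures/b.gbk", "genbank")
census <- lapply(list(a = a, b = b), mite_census, consensus = SYNTHETIC_MITE)
for (g in names(census)) {
  cat("genome", g, ": "); print(census[[g]])
}
copies_tab <- rbind(cbind(genome = "a", census$a$copies),
                    cbind(genome = "b", census$b$copies))
write_report(copies_tab, "results/mite_census.tsv", "tsv")
modal_nt <- unlist(lapply(names(census), function(g) {
  mc <- census[[g]]
  gen <- if (g == "a") a else b
  modal <- mc$copies[mc$copies$length == mc$modal_length, , drop = FALSE]
  vapply(seq_len(nrow(modal)), function(i) {
    s <- substr(gen$sequence, modal$start[i] + 1, modal$end[i])
    if (modal$strand[i] == "-") revcomp(s) else s
  }, "")
}))
if (length(modal_nt) >= 2) {
  cons <- consensus_from_copies(modal_nt)
  writeLines(c(sprintf("> consensus of %d modal-length copies", length(modal_nt)),
               cons$consensus), "results/mite_consensus.txt")
  cat(sprintf("Consensus identical to the generator's element: %s\n",
              identical(cons$consensus, SYNTHETIC_MITE)))
}

## (d) in-silico PCR strain typing -------------------------------------------
# primers flanking each strain-specific block: same pair, different product
truth <- read_report_tsv("results/fixtures/truth.tsv")
blocks <- truth[truth$type == "block_indel", ]
primers <- do.call(rbind, lapply(seq_len(nrow(blocks)), function(i) {
  e <- blocks[i, ]
  # anchor on the genome that carries the block, 150 bp outside it
  g <- if (e$carrier == "a") a else b
  s <- if (e$carrier == "a") e$a_start else e$b_start
  en <- if (e$carrier == "a") e$a_end else e$b_end
  data.frame(id = sprintf("block_%02d", i),
             forward_seq = substr(g$sequence, s - 150 + 1, s - 150 + 22),
             reverse_seq = revcomp(substr(g$sequence, en + 129, en + 150)))
}))
write_report(primers, "results/primers.tsv", "tsv")
tab <- pcr_table(a, b, primers, max_product = 10000L)
write_report(tab, "results/pcr_products.tsv", "tsv")
cat("\nDiagnostic PCR products (bp) per strain:\n")
print(tab)
cat("Wrote cds_comparison.txt, rrna_pairs.tsv, mite_census.tsv, mite_consensus.txt,\n",
    "primers.tsv and pcr_products.tsv to results/\n")
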
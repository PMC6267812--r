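#!/usr/bin/env Rscript
# Step 7 (optional; requires a one-off ~17 MB download) — full-scale
# reproduction on the published chromosomes.
#
# Download the three accessions as FASTA or GenBank into reference_genomes/
# (BX470251.fasta, CP024901.fasta, CP024900.fasta — GenBank flat files named
# <accession>.gbk additionally enable the rpoB comparison), then run this
# step. It reports the number of difference positions between the two TT01
# assemblies, and the matchSEG/divSEG statistics of the TT01m vs DJC
# comparison. Expect roughly 10-40 min on one CPU.

library(pairseg)

files <- reference_genome_files()
if (any(is.na(files$path))) {
  cat("Reference chromosomes not found under 'reference_genomes/'.\n",
      "Download BX470251, CP024901 and CP024900 (FASTA or GenBank) first.\n")
  quit(status = 1)
}

res <- reproduce_reference_comparison()

cat(sprintf("TT01 vs TT01m: %d difference positions\n",
            res$tt01_vs_tt01m$n_differences))
write_report(as.data.frame(res$tt01_vs_tt01m$diffs),
             "results/reference_tt01_diffs.tsv", "tsv")

st <- res$stats
cat(sprintf(paste0(
  "TT01m vs DJC: %d matchSEGs, %d divSEGs; cumulative identity %.4f;\n",
  "coverage %.1f%% / %.1f%%; %d point mutations; %d one-base indels;\n",
  "divSEG totals %d bp / %d bp\n"),
  st$n_matchseg, st$n_divseg, st$cumulative_identity,
  100 * st$a_match_coverage, 100 * st$b_match_coverage,
  st$n_point_mutations, st$n_one_base_indels,
  st$a_div_bases, st$b_div_bases))
write_report(segment_table(res$segmentation), "results/reference_segments.tsv", "tsv")

if (!is.null(res$rpob)) print(res$rpob)
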
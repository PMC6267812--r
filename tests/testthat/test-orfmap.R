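# orfmap: positional ORF correlation, start-codon reconciliation, disrupted
# and strain-specific gene sets

orf_fixture <- function(seed = 61L, ...) {
  spec <- mutation_spec(genome_length = 60000L, n_snp = 5L, n_1bp_indel = 2L,
                        n_frameshift = 2L, n_inversion = 0L, n_tandem_cnv = 0L,
                        n_mge_insertion = 0L, n_block_indel = 2L,
                        block_length_range = c(4000L, 6000L),
                        n_unique_genes = 5L, n_dup_genes = 2L, seed = seed, ...)
  pair <- generate_pair(spec)
  seg <- compare_genomes(pair$a, pair$b, chunk = 60000)
  list(pair = pair, seg = seg, posmap = build_position_map(seg))
}
FIX <- orf_fixture()

test_that("identical genomes with identical annotations correlate all perfect", {
  spec <- mutation_spec(genome_length = 30000L, n_snp = 0L, n_1bp_indel = 0L,
                        n_frameshift = 0L, n_inversion = 0L, n_tandem_cnv = 0L,
                        n_mge_insertion = 0L, n_block_indel = 0L,
                        n_unique_genes = 0L, n_dup_genes = 0L, seed = 62L)
  pair <- generate_pair(spec)
  expect_identical(pair$a$sequence, pair$b$sequence)
  pm <- build_position_map(compare_genomes(pair$a, pair$b, chunk = 30000))
  oc <- correlate_orfs(pair$a, pair$b, pm)
  expect_true(all(oc$status == "perfect"))
  expect_true(all(oc$name_match))
  expect_equal(nrow(oc), sum(pair$a$features$kind == "CDS"))
})

test_that("every CDS of either genome appears in exactly one correlation row", {
  oc <- correlate_orfs(FIX$pair$a, FIX$pair$b, FIX$posmap)
  a_cds <- FIX$pair$a$features$locus_tag[FIX$pair$a$features$kind == "CDS"]
  b_cds <- FIX$pair$b$features$locus_tag[FIX$pair$b$features$kind == "CDS"]
  expect_setequal(oc$a_locus[!is.na(oc$a_locus)], a_cds)
  expect_setequal(oc$b_locus[!is.na(oc$b_locus)], b_cds)
  expect_false(anyDuplicated(oc$a_locus, incomparables = NA) > 0)
  expect_false(anyDuplicated(oc$b_locus, incomparables = NA) > 0)
})

test_that("CDSs inside strain-specific blocks are classified strain_specific", {
  oc <- correlate_orfs(FIX$pair$a, FIX$pair$b, FIX$posmap)
  planted <- FIX$pair$planted_genes$locus_tag
  got <- oc$status[match(planted, ifelse(is.na(oc$a_locus), oc$b_locus, oc$a_locus))]
  expect_true(all(got == "strain_specific"))
})

test_that("the correlation relation is symmetric", {
  oc_ab <- correlate_orfs(FIX$pair$a, FIX$pair$b, FIX$posmap)
  # swap the roles by rebuilding the position map in the reverse direction
  seg_ba <- compare_genomes(FIX$pair$b, FIX$pair$a, chunk = 60000)
  oc_ba <- correlate_orfs(FIX$pair$b, FIX$pair$a, build_position_map(seg_ba))
  pairs_ab <- oc_ab[!is.na(oc_ab$a_locus) & !is.na(oc_ab$b_locus),
                    c("a_locus", "b_locus")]
  pairs_ba <- oc_ba[!is.na(oc_ba$a_locus) & !is.na(oc_ba$b_locus),
                    c("b_locus", "a_locus")]
  names(pairs_ba) <- c("a_locus", "b_locus")
  ord <- function(d) d[order(d$a_locus), ]
  expect_equal(ord(pairs_ab), ord(pairs_ba), ignore_attr = TRUE)
})

test_that("protein identity verification applies the start-codon rules", {
  set.seed(63)
  body <- paste(sample(setdiff(c(outer(outer(c("A","C","G","T"), c("A","C","G","T"), paste0),
                                       c("A","C","G","T"), paste0)),
                               c("TAA","TAG","TGA")), 60, replace = TRUE),
                collapse = "")
  long_nt <- paste0("ATG", "GTA", body, "TAA")       # Met-Val-...
  # shorter ORF starts 1 codon downstream, GTG start over the internal Val
  short_gtg <- paste0("GTG", body, "TAA")
  expect_true(verify_sequence_identity(long_nt, short_gtg))
  # with an ATG start the fragment must match as-is: V != M
  short_atg <- paste0("ATG", body, "TAA")
  expect_false(verify_sequence_identity(long_nt, short_atg))
  # identical CDSs
  expect_true(verify_sequence_identity(long_nt, long_nt))
  # a nonsynonymous substitution breaks identity
  mut <- long_nt
  substr(mut, 10, 12) <- if (substr(long_nt, 10, 12) == "TGG") "TGT" else "TGG"
  expect_false(verify_sequence_identity(long_nt, mut))
  # untranslatable input is flagged, not judged
  expect_warning(res <- verify_sequence_identity("ATGAA", "ATGAA"), "multiple of 3")
  expect_true(is.na(res))
})

test_that("seeded frameshifts surface as split disrupted pairs", {
  oc <- correlate_orfs(FIX$pair$a, FIX$pair$b, FIX$posmap)
  dis <- find_disrupted(oc, FIX$pair$a, FIX$pair$b, FIX$posmap)
  fs <- FIX$pair$truth[startsWith(FIX$pair$truth$type, "frameshift"), ]
  expect_equal(nrow(dis), nrow(fs))
  expect_setequal(dis$regular_locus, fs$locus)
  expect_true(all(dis$kind == "split"))
  # the regular copy sits in the genome opposite the frameshift carrier
  expect_equal(sort(dis$regular_genome),
               sort(ifelse(fs$carrier == "a", "b", "a")))
})

test_that("a pseudo-flagged partner makes a disrupted pair; pseudo on both sides is excluded", {
  spec <- mutation_spec(genome_length = 20000L, n_snp = 0L, n_1bp_indel = 0L,
                        n_frameshift = 0L, n_inversion = 0L, n_tandem_cnv = 0L,
                        n_mge_insertion = 0L, n_block_indel = 0L,
                        n_unique_genes = 0L, n_dup_genes = 0L, seed = 64L)
  pair <- generate_pair(spec)
  a <- pair$a; b <- pair$b
  b$features$pseudo[1] <- TRUE            # disrupted in b only
  a$features$pseudo[2] <- TRUE            # disrupted in both
  b$features$pseudo[2] <- TRUE
  pm <- build_position_map(compare_genomes(a, b, chunk = 20000))
  oc <- correlate_orfs(a, b, pm)
  dis <- find_disrupted(oc, a, b, pm)
  expect_equal(nrow(dis), 1L)
  expect_equal(dis$kind, "pseudo")
  expect_equal(dis$regular_genome, "a")
  expect_equal(dis$regular_locus, a$features$locus_tag[1])
})

test_that("the 75% homolog filter retains exactly the seeded unique genes", {
  oc <- correlate_orfs(FIX$pair$a, FIX$pair$b, FIX$posmap)
  filt <- strain_specific_filter(oc, FIX$pair$a, FIX$pair$b)
  pg <- FIX$pair$planted_genes
  uniq <- pg$locus_tag[pg$role == "unique"]
  dup <- pg$locus_tag[pg$role == "dup"]
  expect_setequal(c(filt$a_specific, filt$b_specific), uniq)
  expect_true(all(dup %in% filt$log$locus[filt$log$decision == "excluded_homolog"]))
})

test_that("keyword categories are excluded from the strain-specific lists", {
  pairx <- FIX$pair
  pg <- pairx$planted_genes
  tag <- pg$locus_tag[pg$role == "unique"][1]
  for (g in c("a", "b")) {
    i <- match(tag, pairx[[g]]$features$locus_tag)
    if (!is.na(i)) pairx[[g]]$features$product_name[i] <- "IS630 family transposase"
  }
  oc <- correlate_orfs(pairx$a, pairx$b, FIX$posmap)
  filt <- strain_specific_filter(oc, pairx$a, pairx$b)
  expect_false(tag %in% c(filt$a_specific, filt$b_specific))
  expect_true(tag %in% filt$log$locus[filt$log$decision == "excluded_keyword"])
})
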
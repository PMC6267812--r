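# gene_tools: CDS mutation typing, rRNA comparison, element census, PCR

test_that("compare_cds counts silent and non-silent point mutations", {
  set.seed(71)
  a <- paste0("ATG", paste(sample(setdiff(names(Biostrings::getGeneticCode("11")),
                                          c("TAA", "TAG", "TGA")), 60,
                                  replace = TRUE), collapse = ""), "TAA")
  expect_equal(compare_cds(a, a)$n_point_mutations, 0L)
  # synonymous change at codon 10: CTx codons all encode Leu
  b <- a
  substr(b, 28, 30) <- "CTA"; substr(a, 28, 30) <- "CTG"
  cc <- compare_cds(a, b)
  expect_equal(cc$n_point_mutations, 1L)
  expect_equal(cc$n_silent, 1L)
  expect_length(cc$aa_replacements, 0L)
  # non-synonymous: His -> Tyr (CAT -> TAT), labelled on protein a
  substr(b, 31, 33) <- "TAT"; substr(a, 31, 33) <- "CAT"
  cc2 <- compare_cds(a, b)
  expect_equal(cc2$n_nonsilent, 1L)
  expect_equal(cc2$aa_replacements, "H11Y")
  expect_equal(cc2$n_silent + cc2$n_nonsilent, cc2$n_point_mutations)
  # symmetric up to label direction
  cc3 <- compare_cds(b, a)
  expect_equal(cc3$aa_replacements, "Y11H")
  expect_error(compare_cds("ATGA", "ATGA"), "multiple of 3")
})

test_that("a resistance-style CDS comparison reports the seeded replacements", {
  set.seed(72)
  nt <- random_cds_fixture(1100)
  mut <- nt
  # 7 silent + 2 non-silent seeded edits; silent sites forced to a codon
  # with single-base synonyms (Leu CTG -> CTA)
  silent_at <- c(12, 101, 205, 333, 414, 752, 901)
  for (cp in silent_at) {
    substr(nt, cp * 3 - 2, cp * 3) <- "CTG"
    substr(mut, cp * 3 - 2, cp * 3) <- "CTA"
  }
  substr(mut, 526 * 3 - 2, 526 * 3) <- "TAC"  # -> Tyr
  substr(nt, 526 * 3 - 2, 526 * 3) <- "CAC"   # His526
  substr(mut, 995 * 3 - 2, 995 * 3) <- "GGA"  # -> Gly
  substr(nt, 995 * 3 - 2, 995 * 3) <- "GAA"   # Glu995
  cc <- compare_cds(nt, mut)
  expect_equal(cc$n_nonsilent, 2L)
  expect_setequal(cc$aa_replacements, c("H526Y", "E995G"))
  expect_equal(cc$n_silent, length(silent_at))
  expect_equal(cc$n_point_mutations, cc$n_silent + cc$n_nonsilent)
})

test_that("rRNA operon sets pair by position and count base differences", {
  spec <- mutation_spec(genome_length = 40000L, n_snp = 0L, n_1bp_indel = 0L,
                        n_frameshift = 0L, n_inversion = 0L, n_tandem_cnv = 0L,
                        n_mge_insertion = 0L, n_block_indel = 0L,
                        n_unique_genes = 0L, n_dup_genes = 0L,
                        n_rrna = 4L, seed = 73L)
  pair <- generate_pair(spec)
  # identical genomes: all pairs report zero differences
  pm <- build_position_map(compare_genomes(pair$a, pair$b, chunk = 40000))
  rr <- compare_rrna_sets(pair$a, pair$b, pm)
  expect_equal(nrow(rr$pairs), 4L)
  expect_true(all(rr$pairs$n_differences == 0L))
  expect_length(rr$unpaired_a, 0L)
  # seed 3 substitutions into one operon of b
  b <- pair$b
  op <- b$features[b$features$kind == "rRNA", ][2, ]
  seq_b <- b$sequence
  for (p in op$start + c(100L, 400L, 700L)) {
    substr(seq_b, p + 1L, p + 1L) <-
      setdiff(c("A", "C", "G", "T"), substr(seq_b, p + 1L, p + 1L))[1]
  }
  b2 <- genome_record(b$id, seq_b, features = b$features)
  pm2 <- build_position_map(compare_genomes(pair$a, b2, chunk = 40000))
  rr2 <- compare_rrna_sets(pair$a, b2, pm2)
  expect_equal(sort(rr2$pairs$n_differences), c(0L, 0L, 0L, 3L))
})

test_that("mite_census finds implanted copies with thresholds and TA TSDs", {
  set.seed(74)
  g <- random_dna(30000, 0.45)
  at <- c(3000, 8000, 13000, 18000, 23000)
  strands <- c("+", "+", "-", "+", "-")
  for (k in 5:1) {
    el <- SYNTHETIC_MITE
    mpos <- sample(nchar(el), 3)   # up to 3 substitutions per copy
    el <- oracle_substitute(el, mpos)
    if (strands[k] == "-") el <- revcomp(el)
    g <- oracle_insert(g, at[k], paste0("TA", el, "TA"))
  }
  mc <- mite_census(g, SYNTHETIC_MITE)
  expect_equal(mc$n_complete, 5L)
  expect_equal(sort(mc$copies$strand), sort(strands))
  expect_true(all(mc$copies$identity >= 0.8))
  expect_true(all(mc$copies$length >= 0.9 * nchar(SYNTHETIC_MITE)))
  expect_true(all(mc$copies$tsd_ta))
  expect_equal(mc$modal_length, nchar(SYNTHETIC_MITE))
  # copies are non-overlapping
  expect_true(all(mc$copies$start[-1] >= mc$copies$end[-nrow(mc$copies)]))
  # a decayed copy below the identity floor is not counted
  g2 <- oracle_insert(g, 27000,
                      oracle_substitute(SYNTHETIC_MITE, sample(123, 40)))
  expect_equal(mite_census(g2, SYNTHETIC_MITE)$n_complete, 5L)
})

test_that("consensus of mutated copies recovers the ancestral element", {
  set.seed(75)
  anc <- SYNTHETIC_MITE
  copies <- vapply(1:100, function(i) {
    n_mut <- rbinom(1, nchar(anc), 0.02)
    if (n_mut == 0) anc else oracle_substitute(anc, sample(nchar(anc), n_mut))
  }, "")
  cons <- consensus_from_copies(copies)
  expect_equal(cons$consensus, anc)
  expect_equal(dim(cons$frequencies), c(4L, nchar(anc)))
  expect_equal(unname(colSums(cons$frequencies)), rep(1, nchar(anc)))
  # ties break by the fixed base order A < C < G < T
  tie <- consensus_from_copies(c("AAAA", "CCAA"))
  expect_equal(tie$consensus, "AAAA")
  expect_error(consensus_from_copies(c("AA", "AAA")), "equal length")
  expect_error(consensus_from_copies("AA"), "at least 2")
})

test_that("in-silico PCR obeys the product-length law", {
  set.seed(76)
  fwd <- random_dna(20, 0.5); rev <- random_dna(20, 0.5)
  for (gap in c(0, 100, 1000)) {
    tmpl <- paste0(random_dna(500, 0.5), fwd, random_dna(gap, 0.5),
                   revcomp(rev), random_dna(500, 0.5))
    p <- insilico_pcr(tmpl, fwd, rev)
    expect_equal(p$product_length, 40L + gap)
  }
  # absent primer -> no product; beyond max_product -> no product
  expect_equal(nrow(insilico_pcr(random_dna(3000, 0.5), fwd, rev)), 0L)
  tmpl_far <- paste0(random_dna(100, 0.5), fwd, random_dna(6000, 0.5),
                     revcomp(rev), random_dna(100, 0.5))
  expect_equal(nrow(insilico_pcr(tmpl_far, fwd, rev)), 0L)
  # mirrored orientation is found too
  tmpl_rc <- paste0(random_dna(300, 0.5), rev, random_dna(50, 0.5),
                    revcomp(fwd), random_dna(300, 0.5))
  p2 <- insilico_pcr(tmpl_rc, fwd, rev)
  expect_equal(p2$product_length, 90L)
  expect_error(insilico_pcr("ACGT", "ACGT", rev), "15-35")
})

test_that("pcr_table reports per-genome product lengths with NA for no product", {
  set.seed(77)
  fwd <- random_dna(20, 0.5); rev <- random_dna(20, 0.5)
  ga <- paste0(random_dna(400, 0.5), fwd, random_dna(200, 0.5),
               revcomp(rev), random_dna(400, 0.5))
  gb <- paste0(random_dna(400, 0.5), fwd, random_dna(700, 0.5),
               revcomp(rev), random_dna(400, 0.5))
  primers <- data.frame(id = c("cand1", "cand2"),
                        forward_seq = c(fwd, random_dna(20, 0.5)),
                        reverse_seq = c(rev, random_dna(20, 0.5)))
  tab <- pcr_table(ga, gb, primers)
  expect_equal(tab$length_a, c(240L, NA))
  expect_equal(tab$length_b, c(740L, NA))
})
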
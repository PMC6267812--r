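# divseg_classifier: category assignment and tandem-repeat detection

test_that("a clean one-sided divSEG is an indel carried by the full side", {
  set.seed(51)
  ins <- random_dna(1200, 0.45)
  call <- classify_divseg(ins, "")
  expect_equal(call$category, "indel")
  expect_equal(call$carrier, "a")
  call2 <- classify_divseg("", ins)
  expect_equal(call2$carrier, "b")
})

test_that("up to 10 unaligned bases on the short side make an approximate insert", {
  set.seed(52)
  call <- classify_divseg(random_dna(7, 0.5), random_dna(900, 0.5))
  expect_equal(call$category, "approximate_insert")
  expect_equal(call$carrier, "b")
  call10 <- classify_divseg(random_dna(10, 0.5), random_dna(500, 0.5))
  expect_equal(call10$category, "approximate_insert")
  # 11 unaligned bases are past the tolerance
  call11 <- classify_divseg(random_dna(11, 0.5), random_dna(500, 0.5))
  expect_equal(call11$category, "replacement")
})

test_that("dissimilar two-sided divSEGs are replacements with measured homology", {
  set.seed(53)
  a_side <- random_dna(600, 0.45)
  b_side <- random_dna(580, 0.45)
  call <- classify_divseg(a_side, b_side)
  expect_equal(call$category, "replacement")
  expect_true(call$homology_identity < 0.8)
  # near-identical sides trigger the matchSEG-review warning tag
  b_close <- oracle_substitute(a_side, c(100, 300, 500))
  call2 <- classify_divseg(a_side, b_close)
  expect_true(call2$homology_identity >= 0.95)
  expect_true("HighIdentityReplacement" %in% call2$tags)
})

test_that("a 12 bp unit at 12 vs 20 copies calls tandem_cnv(12, 20)", {
  set.seed(54)
  unit <- "ATCGGATCCGTA"
  flank1 <- random_dna(400, 0.45); flank2 <- random_dna(400, 0.45)
  ga <- paste0(flank1, strrep(unit, 12), flank2)
  gb <- paste0(flank1, strrep(unit, 20), flank2)
  # the divSEG as segmentation would cut it: the extra copies in b
  call <- classify_divseg("", strrep(unit, 8),
                          a_genome = ga, b_genome = gb,
                          a_start = 400L + 12L * 12L, a_end = 400L + 12L * 12L,
                          b_start = 400L + 12L * 12L, b_end = 400L + 12L * 20L)
  expect_equal(call$category, "tandem_cnv")
  expect_equal(call$a_copies, 12L)
  expect_equal(call$b_copies, 20L)
  expect_equal(nchar(call$unit), 12L)
  expect_true(oracle_is_tandem_of(strrep(call$unit, 3), unit))
})

test_that("tandem_cnv is symmetric up to swapping the copy counts", {
  unit <- "GATTACAC"
  f1 <- strrep("CT", 150); f2 <- strrep("GA", 150)
  ga <- paste0(f1, strrep(unit, 15), f2)
  gb <- paste0(f1, strrep(unit, 31), f2)
  arr_a_end <- 300L + 8L * 15L
  call_ab <- classify_divseg("", strrep(unit, 16), ga, gb,
                             arr_a_end, arr_a_end, arr_a_end, 300L + 8L * 31L)
  call_ba <- classify_divseg(strrep(unit, 16), "", gb, ga,
                             arr_a_end, 300L + 8L * 31L, arr_a_end, arr_a_end)
  expect_equal(call_ab$category, "tandem_cnv")
  expect_equal(call_ba$category, "tandem_cnv")
  expect_equal(call_ab$a_copies, call_ba$b_copies)
  expect_equal(call_ab$b_copies, call_ba$a_copies)
})

test_that("detect_tandem_unit honours its bounds and noise tolerance", {
  # 3 bp unit is below the 7 bp floor
  expect_null(detect_tandem_unit("ATGATGATGATG"))
  # 8 bp unit repeated 47 times exactly
  unit <- "GCGATTAC"
  hit <- detect_tandem_unit(strrep(unit, 47))
  expect_equal(hit$unit_length, 8L)
  expect_equal(hit$copies, 47L)
  expect_true(oracle_is_tandem_of(strrep(hit$unit, 2), unit))
  # 10-copy array with 5% noise still recovers the unit and count
  set.seed(55)
  arr <- strrep("CCGTATTGAC", 10)
  noisy <- oracle_substitute(arr, sample(nchar(arr), round(0.05 * nchar(arr))))
  hit2 <- detect_tandem_unit(noisy)
  expect_false(is.null(hit2))
  expect_equal(hit2$unit_length, 10L)
  expect_equal(hit2$copies, 10L)
  # random sequence has no unit
  expect_null(detect_tandem_unit(random_dna(200, 0.5)))
})

test_that("inserts duplicated elsewhere in their genome are tagged", {
  set.seed(56)
  donor <- random_dna(800, 0.45)
  genome <- paste0(random_dna(3000, 0.45), donor, random_dna(3000, 0.45),
                   donor, random_dna(2000, 0.45))
  # the second copy, treated as the insert under scrutiny
  self_start <- 3000L + 800L + 3000L
  tags <- annotate_internal_repeats(donor, genome, self_start, self_start + 800L)
  expect_equal(tags, "InternallyRepeated")
  # a unique insert is untagged
  tags2 <- annotate_internal_repeats(random_dna(800, 0.45), genome, 0L, 0L)
  expect_length(tags2, 0L)
})

test_that("classify_divsegs recovers seeded categories on a synthetic pair", {
  spec <- mutation_spec(genome_length = 100000L, n_snp = 10L, n_1bp_indel = 2L,
                        n_frameshift = 0L, n_inversion = 0L, n_tandem_cnv = 1L,
                        tandem_unit_range = c(8L, 12L),
                        n_mge_insertion = 2L, n_block_indel = 2L,
                        block_length_range = c(500L, 2000L),
                        n_unique_genes = 0L, n_dup_genes = 0L,
                        gene_grid = FALSE, seed = 77L)
  pair <- generate_pair(spec)
  seg <- compare_genomes(pair$a, pair$b)
  calls <- classify_divsegs(seg)
  # every divSEG gets exactly one category from the fixed vocabulary
  expect_true(all(calls$category %in%
                    c("indel", "approximate_insert", "replacement", "tandem_cnv")))
  tr <- pair$truth
  # the two blocks and two elements arrive as indels/approximate inserts
  n_insert_like <- sum(calls$category %in% c("indel", "approximate_insert"))
  expect_equal(n_insert_like, 4L)
  expect_equal(sum(calls$category == "tandem_cnv"), 1L)
  cnv <- calls[calls$category == "tandem_cnv", ]
  tr_cnv <- tr[tr$type == "tandem_cnv", ]
  carrier_copies <- if (tr_cnv$carrier == "a") cnv$a_copies else cnv$b_copies
  other_copies <- if (tr_cnv$carrier == "a") cnv$b_copies else cnv$a_copies
  expect_equal(carrier_copies, tr_cnv$carrier_copies)
  expect_equal(other_copies, tr_cnv$anc_copies)
})
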
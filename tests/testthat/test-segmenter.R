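# segmenter: chunked traversal, matchSEG/divSEG extraction, refinement

test_that("identical genomes give one matchSEG, zero divSEGs, divergence 0", {
  set.seed(21)
  g <- random_dna(60000, 0.43)
  seg <- compare_genomes(g, g, chunk = 20000)
  tab <- segment_table(seg)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$type, "match")
  expect_equal(tab$divergence, 0)
  st <- segmentation_stats(seg)
  expect_equal(st$n_matchseg, 1L)
  expect_equal(st$n_divseg, 0L)
  expect_equal(st$a_match_coverage, 1)
})

test_that("chunked traversal tiles identical genomes in ceiling(n/emit) chunks", {
  set.seed(22)
  g <- random_dna(50000, 0.43)
  ch <- first_pass(g, g, chunk = 20000)
  expect_equal(length(ch), 3L)
  expect_true(all(vapply(ch, function(x) !grepl("-", x$a_aln, fixed = TRUE), TRUE)))
  # emitted intervals tile [0, n)
  froms <- vapply(ch, function(x) as.integer(x$a_from), 0L)
  tos <- vapply(ch, function(x) as.integer(x$a_to), 0L)
  expect_equal(froms, c(0L, tos[1], tos[2]))
  expect_equal(tos[3], 50000L)
})

test_that("the restart rule records the start of the last matching stretch", {
  set.seed(23)
  a <- random_dna(30000, 0.43)
  # divergence near the middle so the last run of chunk 1 starts past chunk/4
  b <- oracle_substitute(a, seq(9000, 9900, by = 150))
  ch <- first_pass(a, b, chunk = 12000)
  expect_gt(length(ch), 1L)
  r1 <- ch[[1]]
  expect_false(is.na(r1$restart_a))
  expect_equal(r1$a_to, r1$restart_a)    # emission stops at the restart point
  expect_equal(ch[[2]]$a_from, r1$restart_a)
  # the restart point opens an exactly matching stretch
  expect_equal(substr(a, r1$restart_a + 1, r1$restart_a + 50),
               substr(b, r1$restart_b + 1, r1$restart_b + 50))
})

test_that("a long insert falls wholly inside one chunk alignment", {
  set.seed(24)
  a <- random_dna(100000, 0.43)
  b <- oracle_insert(a, 50000, random_dna(30000, 0.43))
  ch <- first_pass(a, b, chunk = 200000)
  expect_equal(length(ch), 1L)
  seg <- compare_genomes(a, b, chunk = 200000)
  tab <- segment_table(seg)
  dv <- tab[tab$type == "div", ]
  expect_equal(nrow(dv), 1L)
  expect_equal(dv$a_start, 50000L)
  expect_equal(dv$b_end - dv$b_start, 30000L)
})

test_that("a 150 bp gap splits a matchSEG; a 90 bp gap is retained internally", {
  set.seed(25)
  a <- random_dna(40000, 0.43)
  b150 <- oracle_insert(a, 20000, random_dna(150, 0.43))
  seg <- compare_genomes(a, b150, chunk = 40000)
  tab <- segment_table(seg)
  expect_equal(sum(tab$type == "match"), 2L)
  expect_equal(sum(tab$type == "div"), 1L)
  b90 <- oracle_insert(a, 20000, random_dna(90, 0.43))
  seg2 <- compare_genomes(a, b90, chunk = 40000)
  tab2 <- segment_table(seg2)
  expect_equal(sum(tab2$type == "match"), 1L)
  expect_equal(sum(tab2$type == "div"), 0L)
  expect_equal(seg2$match$go, 1L)
  expect_equal(seg2$match$ge, 89L)
})

test_that("ten seeded inserts of 101-5000 bp give 11 matchSEGs at truth breakpoints", {
  set.seed(26)
  a <- random_dna(150000, 0.43)
  lens <- c(101, 250, 500, 800, 1200, 1800, 2500, 3200, 4100, 5000)
  at <- seq(12000, 138000, length.out = 10)
  b <- a
  for (k in 10:1) {
    ins <- random_dna(lens[k], 0.43)
    # pin insert edges so flanking exact matches cannot slide into the insert
    substr(ins, 1, 1) <- setdiff(c("A","C","G","T"), substr(a, at[k] + 1, at[k] + 1))[1]
    substr(ins, lens[k], lens[k]) <- setdiff(c("A","C","G","T"), substr(a, at[k], at[k]))[1]
    b <- oracle_insert(b, at[k], ins)
  }
  seg <- compare_genomes(a, b)
  tab <- segment_table(seg)
  expect_equal(sum(tab$type == "match"), 11L)
  dv <- tab[tab$type == "div", ]
  expect_equal(nrow(dv), 10L)
  expect_equal(dv$a_start, as.integer(at))
  expect_equal(dv$b_end - dv$b_start, as.integer(lens))
})

test_that("matchSEG boundaries start and end on a matching base", {
  set.seed(27)
  a <- random_dna(30000, 0.43)
  b <- oracle_insert(oracle_substitute(a, c(14995, 15005)), 15000,
                     random_dna(400, 0.43))
  seg <- compare_genomes(a, b, chunk = 30000)
  alns <- attr(seg$match, "alignments")
  for (al in alns) {
    first <- c(substr(al$a_aln, 1, 1), substr(al$b_aln, 1, 1))
    last <- c(substr(al$a_aln, nchar(al$a_aln), nchar(al$a_aln)),
              substr(al$b_aln, nchar(al$b_aln), nchar(al$b_aln)))
    expect_equal(first[1], first[2])
    expect_equal(last[1], last[2])
    expect_false("-" %in% c(first, last))
  }
})

test_that("refine fuses matchSEGs separated by < 100 bp on both sides", {
  set.seed(28)
  a <- random_dna(20000, 0.43)
  # a 40 <-> 40 bp replaced patch: both sides < 100 bp apart after extraction
  b <- paste0(substr(a, 1, 10000), random_dna(40, 0.43), substr(a, 10041, 20000))
  chunks <- first_pass(a, b, chunk = 20000)
  draft <- extract_segments(chunks)
  refined <- refine(draft)
  tab <- segment_table(refined)
  expect_equal(sum(tab$type == "match"), 1L)
  expect_equal(sum(tab$type == "div"), 0L)
})

test_that("refine is idempotent", {
  set.seed(29)
  a <- random_dna(40000, 0.43)
  b <- oracle_insert(oracle_substitute(a, seq(5000, 35000, by = 5000)),
                     20000, random_dna(900, 0.43))
  seg1 <- compare_genomes(a, b, chunk = 40000)
  seg2 <- refine(seg1)
  expect_equal(seg1$match, seg2$match, ignore_attr = TRUE)
  expect_equal(segment_table(seg1), segment_table(seg2))
})

test_that("partition invariant holds on randomized synthetic pairs", {
  set.seed(30)
  for (rep in 1:10) {
    spec <- mutation_spec(
      genome_length = sample(8000:16000, 1), n_snp = sample(3:10, 1),
      n_1bp_indel = sample(0:3, 1), n_frameshift = 0L, n_inversion = 0L,
      n_tandem_cnv = 0L, n_mge_insertion = sample(0:2, 1),
      n_block_indel = sample(0:2, 1), block_length_range = c(300L, 1500L),
      gene_grid = FALSE, seed = sample.int(10000, 1))
    pair <- generate_pair(spec)
    seg <- compare_genomes(pair$a, pair$b, chunk = 20000)
    tab <- segment_table(seg)
    # disjoint cover of [0, len) for both genomes
    expect_equal(tab$a_start[1], 0L)
    expect_equal(tab$a_end[nrow(tab)], pair$a$length)
    expect_equal(tab$b_end[nrow(tab)], pair$b$length)
    expect_equal(tab$a_start[-1], tab$a_end[-nrow(tab)])
    expect_equal(tab$b_start[-1], tab$b_end[-nrow(tab)])
    # every genome position classified exactly once (by construction of the
    # table, adjacency + ends imply the partition)
  }
})

test_that("high-divergence matchSEGs are flagged, not converted", {
  set.seed(31)
  a <- random_dna(12000, 0.43)
  # a 3% mutated middle stretch: above 1%, below the 5% window cut
  pos <- seq(4000, 8000, by = 33)
  b <- oracle_substitute(a, pos)
  seg <- compare_genomes(a, b, chunk = 12000)
  flagged <- attr(seg$match, "flagged")
  expect_true(length(flagged) >= 1L)
  expect_true(all(seg$match$divergence[flagged] > 0.01))
})
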
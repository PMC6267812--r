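# synthetic_data: the generator and its ground-truth guarantees

test_that("generation is deterministic from the seed", {
  spec <- tiny_spec(seed = 81L)
  p1 <- generate_pair(spec)
  p2 <- generate_pair(spec)
  expect_identical(p1$a$sequence, p2$a$sequence)
  expect_identical(p1$b$sequence, p2$b$sequence)
  expect_identical(p1$truth, p2$truth)
  p3 <- generate_pair(tiny_spec(seed = 82L))
  expect_false(identical(p1$a$sequence, p3$a$sequence))
})

test_that("ancestor GC content is within 3 sd of the binomial expectation", {
  spec <- mutation_spec(genome_length = 100000L, gc_content = 0.5,
                        n_frameshift = 0L, gene_grid = FALSE, seed = 83L)
  anc <- generate_ancestor(spec)
  gc <- sum(strsplit(anc$sequence, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 50000), 3 * sqrt(100000 * 0.25))
})

test_that("degenerate specs are rejected", {
  expect_error(mutation_spec(genome_length = 0L), "genome_length")
  expect_error(mutation_spec(n_snp = -1L), "n_snp")
  expect_error(mutation_spec(n_frameshift = 1L, gene_grid = FALSE), "gene_grid")
  dense <- mutation_spec(genome_length = 3000L, n_snp = 50L, n_1bp_indel = 0L,
                         n_frameshift = 0L, n_inversion = 0L, n_tandem_cnv = 0L,
                         n_mge_insertion = 0L, n_block_indel = 0L,
                         gene_grid = FALSE, seed = 1L)
  expect_error(mutate_pair(generate_ancestor(dense), dense), "infeasible")
})

test_that("zero event counts reproduce the ancestor in both descendants", {
  spec <- mutation_spec(genome_length = 20000L, n_snp = 0L, n_1bp_indel = 0L,
                        n_frameshift = 0L, n_inversion = 0L, n_tandem_cnv = 0L,
                        n_mge_insertion = 0L, n_block_indel = 0L,
                        gene_grid = FALSE, seed = 84L)
  pair <- generate_pair(spec)
  expect_identical(pair$a$sequence, pair$ancestor$sequence)
  expect_identical(pair$b$sequence, pair$ancestor$sequence)
  expect_equal(nrow(pair$truth), 0L)
})

test_that("each event is applied to exactly one descendant at truth coordinates", {
  spec <- mutation_spec(genome_length = 80000L, n_snp = 15L, n_1bp_indel = 4L,
                        n_frameshift = 1L, n_inversion = 1L, n_tandem_cnv = 1L,
                        n_mge_insertion = 2L, n_block_indel = 2L,
                        block_length_range = c(500L, 2000L),
                        n_unique_genes = 2L, n_dup_genes = 1L, seed = 85L)
  pair <- generate_pair(spec)
  tr <- pair$truth
  expect_true(all(tr$carrier %in% c("a", "b")))
  # inserted payloads are literal substrings at the recorded coordinates
  for (i in which(nzchar(tr$payload) & tr$type != "inversion")) {
    g <- pair[[tr$carrier[i]]]
    s <- if (tr$carrier[i] == "a") tr$a_start[i] else tr$b_start[i]
    e <- if (tr$carrier[i] == "a") tr$a_end[i] else tr$b_end[i]
    expect_identical(substr(g$sequence, s + 1, e), tr$payload[i])
  }
  # the non-carrier genome is untouched at each locus: its recorded interval
  # still matches the prepared ancestor (span-type events only; insertion
  # events record an empty point on the non-carrier side)
  span_types <- c("snp", "one_base_deletion", "frameshift_deletion", "inversion")
  for (i in which(tr$type %in% span_types)) {
    other <- setdiff(c("a", "b"), tr$carrier[i])
    g <- pair[[other]]
    s <- if (other == "a") tr$a_start[i] else tr$b_start[i]
    e <- if (other == "a") tr$a_end[i] else tr$b_end[i]
    expect_identical(substr(g$sequence, s + 1, e),
                     substr(pair$ancestor$sequence, tr$anc_start[i] + 1,
                            tr$anc_end[i]))
  }
})

test_that("inversions are bounded by planted inverted repeats", {
  spec <- mutation_spec(genome_length = 50000L, n_snp = 0L, n_1bp_indel = 0L,
                        n_frameshift = 0L, n_inversion = 1L, n_tandem_cnv = 0L,
                        n_mge_insertion = 0L, n_block_indel = 0L,
                        n_unique_genes = 0L, n_dup_genes = 0L, seed = 86L)
  pair <- generate_pair(spec)
  tr <- pair$truth[pair$truth$type == "inversion", ]
  anc <- pair$ancestor$sequence
  ir <- substr(anc, tr$anc_start + 1, tr$anc_start + spec$ir_length)
  tail_ir <- substr(anc, tr$anc_end - spec$ir_length + 1, tr$anc_end)
  expect_identical(tail_ir, revcomp(ir))
  # the carrier holds the reverse complement of the ancestral interval
  g <- pair[[tr$carrier]]
  s <- if (tr$carrier == "a") tr$a_start else tr$b_start
  e <- if (tr$carrier == "a") tr$a_end else tr$b_end
  expect_identical(substr(g$sequence, s + 1, e),
                   revcomp(substr(anc, tr$anc_start + 1, tr$anc_end)))
})

test_that("mobile-element insertions duplicate the TA target site", {
  spec <- mutation_spec(genome_length = 40000L, n_snp = 0L, n_1bp_indel = 0L,
                        n_frameshift = 0L, n_inversion = 0L, n_tandem_cnv = 0L,
                        n_mge_insertion = 3L, n_block_indel = 0L,
                        gene_grid = FALSE, seed = 87L)
  pair <- generate_pair(spec)
  tr <- pair$truth[pair$truth$type == "mge_insertion", ]
  for (i in seq_len(nrow(tr))) {
    g <- pair[[tr$carrier[i]]]$sequence
    s <- if (tr$carrier[i] == "a") tr$a_start[i] else tr$b_start[i]
    e <- if (tr$carrier[i] == "a") tr$a_end[i] else tr$b_end[i]
    # TA | element | TA around the recorded insertion
    expect_identical(substr(g, s - 1, s), "TA")
    expect_identical(substr(g, s + 1, e), paste0(SYNTHETIC_MITE, "TA"))
  }
})

test_that("fixtures are emitted deterministically and round-trip", {
  spec <- tiny_spec(seed = 88L)
  pair <- generate_pair(spec)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- emit_fixture(pair, d1)
  p2 <- emit_fixture(generate_pair(spec), d2)
  for (f in names(p1)) {
    expect_identical(readLines(p1[[f]]), readLines(p2[[f]]),
                     label = paste("fixture file", f))
  }
  # truth TSV row count equals the event count
  tt <- read_report_tsv(p1[["truth"]])
  expect_equal(nrow(tt), nrow(pair$truth))
  # FASTA/GenBank round-trip the sequences and annotations
  back <- read_genome(p1[["a_fasta"]], "fasta")
  expect_identical(back$sequence, pair$a$sequence)
})

test_that("emitted GenBank annotations round-trip for the annotated pair", {
  spec <- mutation_spec(genome_length = 20000L, n_snp = 2L, n_1bp_indel = 0L,
                        n_frameshift = 1L, n_inversion = 0L, n_tandem_cnv = 0L,
                        n_mge_insertion = 0L, n_block_indel = 0L,
                        n_unique_genes = 0L, n_dup_genes = 0L, seed = 89L)
  pair <- generate_pair(spec)
  d <- withr::local_tempdir()
  paths <- emit_fixture(pair, d)
  back <- read_genome(paths[["b_gbk"]], "genbank")
  expect_identical(back$sequence, pair$b$sequence)
  f1 <- pair$b$features[order(pair$b$features$start), ]
  f2 <- back$features[order(back$features$start), ]
  expect_equal(f2$start, f1$start)
  expect_equal(f2$end, f1$end)
  expect_equal(f2$strand, f1$strand)
  expect_equal(f2$locus_tag, f1$locus_tag)
})
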
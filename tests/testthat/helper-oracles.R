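# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: a full Needleman-Wunsch affine DP for alignment
# scores, a naive per-column scan for column statistics, and direct string
# surgery for mutated test pairs.

# full affine-gap DP (Gotoh), returning only the optimal score; penalties as
# in align_params(): a gap of length L costs gap_open + gap_ext * L
oracle_align_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = 4, gap_ext = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # align ca[i] with cb[j]
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (ca[i] against -)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- -gap_open - gap_ext * i
  for (j in seq_len(m)) Y[1, j + 1] <- -gap_open - gap_ext * j
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (ca[i] == cb[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                             X[i, j + 1] - gap_ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                             Y[i + 1, j] - gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# naive per-column scan of a gapped alignment
oracle_column_scan <- function(a_aln, b_aln) {
  ca <- strsplit(a_aln, "")[[1]]
  cb <- strsplit(b_aln, "")[[1]]
  m <- mm <- go <- ge <- 0L
  in_gap_a <- in_gap_b <- FALSE
  for (k in seq_along(ca)) {
    if (ca[k] == "-") {
      if (in_gap_a) ge <- ge + 1L else go <- go + 1L
      in_gap_a <- TRUE; in_gap_b <- FALSE
    } else if (cb[k] == "-") {
      if (in_gap_b) ge <- ge + 1L else go <- go + 1L
      in_gap_b <- TRUE; in_gap_a <- FALSE
    } else {
      in_gap_a <- in_gap_b <- FALSE
      if (ca[k] == cb[k] && ca[k] != "N") m <- m + 1L else mm <- mm + 1L
    }
  }
  list(m = m, mm = mm, go = go, ge = ge)
}

# apply isolated substitutions at given 1-based positions (direct surgery)
oracle_substitute <- function(s, pos, alt = NULL) {
  ch <- strsplit(s, "")[[1]]
  for (k in seq_along(pos)) {
    p <- pos[k]
    ch[p] <- if (is.null(alt)) setdiff(c("A", "C", "G", "T"), ch[p])[1] else alt[k]
  }
  paste(ch, collapse = "")
}

oracle_insert <- function(s, pos, payload) {
  paste0(substr(s, 1, pos), payload, substr(s, pos + 1, nchar(s)))
}

oracle_delete <- function(s, pos, len = 1) {
  paste0(substr(s, 1, pos), substr(s, pos + len + 1, nchar(s)))
}

# exhaustive tandem-unit scan: does `s` consist of >= 90%-clean tandem copies
# of some rotation of `unit`?
oracle_is_tandem_of <- function(s, unit) {
  u <- nchar(unit)
  rots <- vapply(seq_len(u), function(k)
    paste0(substr(unit, k, u), substr(unit, 1, k - 1)), "")
  for (r in rots) {
    tiled <- strrep(r, ceiling(nchar(s) / u))
    tiled <- substr(tiled, 1, nchar(s))
    if (mean(strsplit(tiled, "")[[1]] == strsplit(s, "")[[1]]) >= 0.9) return(TRUE)
  }
  FALSE
}

# fixture CDS of n_codon codons (ATG start, sense body, TAA stop)
random_cds_fixture <- function(n_codon) {
  nt <- c("A", "C", "G", "T")
  sense <- setdiff(as.vector(outer(outer(nt, nt, paste0), nt, paste0)),
                   c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(sense, n_codon - 2, replace = TRUE), collapse = ""),
         "TAA")
}

# a synonymous codon under the bacterial code, or NA if the codon is unique
synonym_of <- function(codon) {
  code <- Biostrings::getGeneticCode("11")
  alt <- setdiff(names(code)[code == code[[codon]]], codon)
  if (length(alt)) alt[1] else NA_character_
}

# small deterministic genome pair for reuse (built once per test file load)
tiny_spec <- function(...) {
  mutation_spec(genome_length = 30000L, n_snp = 8L, n_1bp_indel = 2L,
                n_frameshift = 0L, n_inversion = 0L, n_tandem_cnv = 0L,
                n_mge_insertion = 0L, n_block_indel = 0L, gene_grid = FALSE,
                ...)
}
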
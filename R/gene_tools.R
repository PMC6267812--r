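# gene_tools: gene-level diagnostics — CDS point-mutation typing, position-
# correlated rRNA operon comparison, mobile-element census and consensus,
# and in-silico PCR strain typing.

#' Compare two in-frame CDS sequences codon by codon
#'
#' Counts point mutations (differing bases) between two CDSs of equal length
#' and classifies each as silent or non-silent by the codon it falls in
#' (a codon whose amino acid changes makes all its differing bases
#' non-silent). Amino acid replacements are reported as
#' `<refAA><position><altAA>` with 1-based residue numbering on the
#' genome-a protein.
#'
#' @param a_cds,b_cds in-frame CDS nucleotide sequences (reading orientation).
#' @return list of class `cds_comparison`: `n_point_mutations`, `n_silent`,
#'   `n_nonsilent`, `aa_replacements` (character vector), `internal_stop`
#'   flag.
#' @export
compare_cds <- function(a_cds, b_cds) {
  a_cds <- toupper(a_cds); b_cds <- toupper(b_cds)
  if (nchar(a_cds) %% 3L != 0L || nchar(b_cds) %% 3L != 0L) {
    stop("CDS length not a multiple of 3", call. = FALSE)
  }
  if (nchar(a_cds) != nchar(b_cds)) {
    stop("compare_cds expects indel-free CDSs of equal length", call. = FALSE)
  }
  code <- Biostrings::getGeneticCode(BACTERIAL_CODE)
  n_codon <- nchar(a_cds) %/% 3L
  ca <- substring(a_cds, 3L * (seq_len(n_codon) - 1L) + 1L, 3L * seq_len(n_codon))
  cb <- substring(b_cds, 3L * (seq_len(n_codon) - 1L) + 1L, 3L * seq_len(n_codon))
  diff_codon <- which(ca != cb)
  n_mut <- 0L; n_silent <- 0L; n_nonsilent <- 0L
  repl <- character()
  internal_stop <- FALSE
  for (k in diff_codon) {
    nd <- sum(strsplit(ca[k], "")[[1L]] != strsplit(cb[k], "")[[1L]])
    aa_a <- code[[ca[k]]]; aa_b <- code[[cb[k]]]
    if (is.null(aa_a) || is.null(aa_b)) next
    n_mut <- n_mut + nd
    if (identical(aa_a, aa_b)) {
      n_silent <- n_silent + nd
    } else {
      n_nonsilent <- n_nonsilent + nd
      if (k < n_codon && (aa_a == "*" || aa_b == "*")) internal_stop <- TRUE
      repl <- c(repl, sprintf("%s%d%s", aa_a, k, aa_b))
    }
  }
  structure(list(n_point_mutations = n_mut, n_silent = n_silent,
                 n_nonsilent = n_nonsilent, aa_replacements = repl,
                 internal_stop = internal_stop),
            class = "cds_comparison")
}

#' @export
print.cds_comparison <- function(x, ...) {
  cat(sprintf("<cds_comparison> %d point mutation(s): %d silent, %d non-silent%s\n",
              x$n_point_mutations, x$n_silent, x$n_nonsilent,
              if (length(x$aa_replacements))
                paste0(" (", paste(x$aa_replacements, collapse = ", "), ")") else ""))
  invisible(x)
}

#' Compare the rRNA operon sets of two genomes at equivalent positions
#'
#' Pairs the rRNA features of the two genomes through the position map
#' (an `a` operon pairs with the `b` operon containing the mapped coordinate
#' of its midpoint) and reports the base-difference count of each pair from
#' a global alignment. Unpaired operons are listed separately.
#'
#' @param a,b annotated [genome_record()]s with rRNA features.
#' @param posmap the pair's `position_map`.
#' @param params [align_params()].
#' @return list: `pairs` (data.frame `a_locus`, `b_locus`, `n_differences`),
#'   `unpaired_a`, `unpaired_b` (locus tags).
#' @export
compare_rrna_sets <- function(a, b, posmap, params = align_params()) {
  fa <- a$features[a$features$kind == "rRNA", , drop = FALSE]
  fb <- b$features[b$features$kind == "rRNA", , drop = FALSE]
  used_b <- rep(FALSE, nrow(fb))
  rows <- list()
  unpaired_a <- character()
  for (i in seq_len(nrow(fa))) {
    mid <- (fa$start[i] + fa$end[i]) %/% 2L
    mp <- posmap$a$partner[mid + 1L]
    j <- NA_integer_
    if (!is.na(mp)) {
      cand <- which(fb$start <= mp & fb$end > mp & !used_b)
      if (length(cand)) j <- cand[1L]
    }
    if (is.na(j)) { unpaired_a <- c(unpaired_a, fa$locus_tag[i]); next }
    used_b[j] <- TRUE
    sa <- cds_sequence(a, fa[i, ]); sb <- cds_sequence(b, fb[j, ])
    nd <- if (identical(sa, sb)) 0L else {
      aln <- align_pair(sa, sb, params)
      cs <- classify_columns(aln)
      cs$mm + cs$go + cs$ge
    }
    rows[[length(rows) + 1L]] <- data.frame(
      a_locus = fa$locus_tag[i], b_locus = fb$locus_tag[j], n_differences = nd)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a_locus = character(), b_locus = character(),
               n_differences = integer())
  rownames(pairs) <- NULL
  list(pairs = pairs, unpaired_a = unpaired_a,
       unpaired_b = fb$locus_tag[!used_b])
}

#' Census of a mobile element in a genome
#'
#' Finds all non-overlapping occurrences of a consensus element on both
#' strands. A copy is accepted when its aligned span is at least
#' `min_length_frac` of the consensus length at `min_identity` identity or
#' better. A flanking TA target-site duplication is recorded when the copy
#' is immediately preceded and followed by `TA`.
#'
#' @param genome a [genome_record()] or DNA string.
#' @param consensus element consensus sequence (>= 50 bp).
#' @param min_length_frac,min_identity completeness thresholds.
#' @return list of class `mite_census`: `copies` (data.frame `start`, `end`,
#'   `strand`, `length`, `identity`, `tsd_ta`), `n_complete`,
#'   `length_histogram` (table), `modal_length`.
#' @export
mite_census <- function(genome, consensus, min_length_frac = 0.9,
                        min_identity = 0.8) {
  s <- genome_seq(genome)
  consensus <- validate_dna(consensus, "consensus")
  L <- nchar(consensus)
  if (L < 50L) stop("consensus must be at least 50 bp", call. = FALSE)
  subj <- Biostrings::DNAString(s)
  max_mm <- floor((1 - min_identity) * L)
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") consensus else revcomp(consensus)
    mt <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                   max.mismatch = max_mm, with.indels = TRUE)
    if (length(mt) == 0L) next
    st <- BiocGenerics::start(mt) - 1L
    en <- BiocGenerics::end(mt)
    for (k in seq_along(st)) {
      w <- substr0(s, st[k], en[k])
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(pat), Biostrings::DNAString(w), type = "global")
      id <- alignment_identity(list(
        a_aln = as.character(Biostrings::alignedPattern(aln)),
        b_aln = as.character(Biostrings::alignedSubject(aln))))
      span <- en[k] - st[k]
      if (span >= min_length_frac * L && !is.na(id) && id >= min_identity) {
        tsd <- identical(substr0(s, max(st[k] - 2L, 0L), st[k]), "TA") &&
          identical(substr0(s, en[k], min(en[k] + 2L, nchar(s))), "TA")
        hits[[length(hits) + 1L]] <- data.frame(
          start = st[k], end = en[k], strand = strand,
          length = span, identity = id, tsd_ta = tsd)
      }
    }
  }
  copies <- if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(), end = integer(), strand = character(),
               length = integer(), identity = numeric(), tsd_ta = logical())
  copies <- copies[order(copies$start), , drop = FALSE]
  # enforce non-overlap, best identity first
  if (nrow(copies) > 1L) {
    keep <- rep(TRUE, nrow(copies))
    ord <- order(-copies$identity, copies$start)
    taken <- matrix(numeric(0), ncol = 2)
    for (i in ord) {
      ov <- nrow(taken) > 0 &&
        any(copies$start[i] < taken[, 2] & copies$end[i] > taken[, 1])
      if (ov) keep[i] <- FALSE
      else taken <- rbind(taken, c(copies$start[i], copies$end[i]))
    }
    copies <- copies[keep, , drop = FALSE]
  }
  rownames(copies) <- NULL
  hist <- table(copies$length)
  modal <- if (nrow(copies)) as.integer(names(hist)[which.max(hist)]) else NA_integer_
  structure(list(copies = copies, n_complete = nrow(copies),
                 length_histogram = hist, modal_length = modal),
            class = "mite_census")
}

#' @export
print.mite_census <- function(x, ...) {
  cat(sprintf("<mite_census> %d complete cop%s, modal length %s bp\n",
              x$n_complete, if (x$n_complete == 1) "y" else "ies",
              ifelse(is.na(x$modal_length), "NA", x$modal_length)))
  invisible(x)
}

#' Consensus and base frequencies of equal-length element copies
#'
#' Per-column majority base; ties are broken by the fixed base order
#' A < C < G < T.
#'
#' @param copies character vector of equal-length DNA strings (>= 2).
#' @return list: `consensus` string, `frequencies` (4 x L matrix of base
#'   frequencies, rows A/C/G/T).
#' @export
consensus_from_copies <- function(copies) {
  if (length(copies) < 2L) stop("need at least 2 copies", call. = FALSE)
  if (length(unique(nchar(copies))) != 1L) {
    stop("copies must have equal length; pre-filter to the modal length",
         call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(copies), "", fixed = TRUE))
  bases <- c("A", "C", "G", "T")
  freq <- apply(mat, 2L, function(col) {
    tb <- table(factor(col, levels = bases))
    as.numeric(tb) / length(col)
  })
  rownames(freq) <- bases
  cons <- bases[apply(freq, 2L, which.max)]   # which.max keeps A<C<G<T on ties
  list(consensus = paste(cons, collapse = ""), frequencies = freq)
}

#' Predict PCR products of a primer pair on a genome
#'
#' Locates the forward primer on the plus strand and the reverse primer's
#' reverse complement downstream on the plus strand (and the mirrored
#' orientation), and reports every product up to `max_product` bp. The
#' product length is the span from the forward primer's 5' genome coordinate
#' to the reverse primer's 3' genome coordinate, inclusive. Primer matching
#' allows up to `max_mismatches` mismatches but never at the 3'-terminal
#' base.
#'
#' @param genome a [genome_record()] or DNA string.
#' @param fwd,rev primer sequences, 15-35 nt, written 5'->3'.
#' @param max_mismatches tolerated mismatches per primer (0-3).
#' @param max_product maximum amplicon length in bp.
#' @return data.frame with `product_length`, `start`, `end` (0-based
#'   half-open amplicon span), `orientation`; zero rows when no product.
#' @export
insilico_pcr <- function(genome, fwd, rev, max_mismatches = 0L,
                         max_product = 5000L) {
  s <- genome_seq(genome)
  fwd <- validate_dna(fwd, "forward primer")
  rev <- validate_dna(rev, "reverse primer")
  if (nchar(fwd) < 15L || nchar(fwd) > 35L || nchar(rev) < 15L || nchar(rev) > 35L) {
    stop("primers must be 15-35 nt", call. = FALSE)
  }
  if (max_mismatches < 0L || max_mismatches > 3L) {
    stop("max_mismatches must be 0-3", call. = FALSE)
  }
  subj <- Biostrings::DNAString(s)
  # primer site on the plus strand; the 3' base of the primer must match
  sites <- function(primer, sense) {
    pat <- if (sense) primer else revcomp(primer)
    mt <- Biostrings::matchPattern(Biostrings::DNAString(pat), subj,
                                   max.mismatch = max_mismatches)
    st <- BiocGenerics::start(mt) - 1L; en <- BiocGenerics::end(mt)
    if (length(st) == 0L) return(data.frame(start = integer(), end = integer()))
    ok <- vapply(seq_along(st), function(k) {
      # 3' terminal base: last base for sense placement, first for antisense
      if (sense) substr0(s, en[k] - 1L, en[k]) == substr(pat, nchar(pat), nchar(pat))
      else substr0(s, st[k], st[k] + 1L) == substr(pat, 1L, 1L)
    }, TRUE)
    data.frame(start = st[ok], end = en[ok])
  }
  products <- list()
  pair_up <- function(f_sites, r_sites, orientation) {
    for (i in seq_len(nrow(f_sites))) {
      down <- r_sites[r_sites$start >= f_sites$end[i] &
                        r_sites$end - f_sites$start[i] <= max_product, , drop = FALSE]
      for (j in seq_len(nrow(down))) {
        products[[length(products) + 1L]] <<- data.frame(
          product_length = down$end[j] - f_sites$start[i],
          start = f_sites$start[i], end = down$end[j],
          orientation = orientation)
      }
    }
  }
  pair_up(sites(fwd, TRUE), sites(rev, FALSE), "fwd_plus")
  pair_up(sites(rev, TRUE), sites(fwd, FALSE), "rev_plus")
  out <- if (length(products)) do.call(rbind, products) else
    data.frame(product_length = integer(), start = integer(), end = integer(),
               orientation = character())
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run a primer table against two genomes
#'
#' @param a,b [genome_record()]s or DNA strings.
#' @param primers data.frame with columns `id`, `forward_seq`, `reverse_seq`.
#' @param ... passed to [insilico_pcr()].
#' @return data.frame: `id`, `length_a`, `length_b` (NA where no product;
#'   the shortest product where several).
#' @export
pcr_table <- function(a, b, primers, ...) {
  one <- function(genome, fwd, rev) {
    p <- insilico_pcr(genome, fwd, rev, ...)
    if (nrow(p) == 0L) NA_integer_ else min(p$product_length)
  }
  data.frame(
    id = primers$id,
    length_a = vapply(seq_len(nrow(primers)), function(i)
      one(a, primers$forward_seq[i], primers$reverse_seq[i]), integer(1)),
    length_b = vapply(seq_len(nrow(primers)), function(i)
      one(b, primers$forward_seq[i], primers$reverse_seq[i]), integer(1)))
}
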
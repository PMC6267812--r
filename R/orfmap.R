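# orfmap: correlate protein-coding genes between two annotated genomes via
# the position-correlation map, reconcile start codons, verify protein
# identity, and derive disrupted and strain-specific gene sets.

BACTERIAL_CODE <- "11"

# 0-based coordinate of the N-terminal (start) and C-terminal (stop) base of
# a CDS on the forward strand, strand-aware
cds_termini <- function(f) {
  n_term <- ifelse(f$strand == "+", f$start, f$end - 1L)
  c_term <- ifelse(f$strand == "+", f$end - 1L, f$start)
  data.frame(n_term = n_term, c_term = c_term)
}

#' Correlate the protein-coding genes of two annotated genomes
#'
#' Attempts to pair every CDS of genome `a` with a CDS of genome `b` by the
#' positional correlation of its termini: C-terminal positions first, then
#' N-terminal positions for the remainder. A correlation is possible only if
#' at least one terminus lies within a matchSEG. A pair whose two termini
#' both map to equivalent positions (0 bp slack), lie in the same matchSEG,
#' and whose product names are identical is `perfect`; pairs correlated by
#' one terminus are `c_term_only` / `n_term_only`, and a pair whose both
#' termini correlate but whose product names differ (or whose termini lie in
#' different segments) also keeps the terminus-level status, with
#' `name_match` recording the disagreement. A CDS lying entirely in
#' strain-specific sequence is `strain_specific`; anything else unpaired is
#' `unmapped`.
#'
#' @param a,b [genome_record()]s with CDS features.
#' @param posmap a `position_map` from [build_position_map()] for this pair.
#' @return data.frame of class `orf_correlation`: `a_locus`, `b_locus`,
#'   `status`, `name_match`, one row per correlation; every CDS of either
#'   genome appears in exactly one row.
#' @export
correlate_orfs <- function(a, b, posmap) {
  fa <- a$features[a$features$kind == "CDS", , drop = FALSE]
  fb <- b$features[b$features$kind == "CDS", , drop = FALSE]
  if (anyDuplicated(fa$locus_tag) || anyDuplicated(fb$locus_tag)) {
    stop("duplicate locus tags", call. = FALSE)
  }
  ta <- cds_termini(fa); tb <- cds_termini(fb)

  # b-side lookup: terminus coordinate+strand -> row
  key <- function(pos, strand) paste0(pos, strand)
  b_by_c <- setNames(seq_len(nrow(fb)), key(tb$c_term, fb$strand))
  b_by_n <- setNames(seq_len(nrow(fb)), key(tb$n_term, fb$strand))

  n_a <- nrow(fa); n_b <- nrow(fb)
  a_partner <- rep(NA_integer_, n_a)
  b_taken <- rep(FALSE, n_b)
  a_via <- rep(NA_character_, n_a)

  map_term <- function(pos) {
    if (posmap$a$category[pos + 1L] != "mapped") return(NA_integer_)
    posmap$a$partner[pos + 1L]
  }
  # pass 1: C-terminal correlation
  for (i in seq_len(n_a)) {
    mp <- map_term(ta$c_term[i])
    if (is.na(mp)) next
    j <- b_by_c[key(mp, fa$strand[i])]
    if (!is.na(j) && !b_taken[j]) {
      a_partner[i] <- j; b_taken[j] <- TRUE; a_via[i] <- "c"
    }
  }
  # pass 2: N-terminal correlation for the remainder
  for (i in which(is.na(a_partner))) {
    mp <- map_term(ta$n_term[i])
    if (is.na(mp)) next
    j <- b_by_n[key(mp, fa$strand[i])]
    if (!is.na(j) && !b_taken[j]) {
      a_partner[i] <- j; b_taken[j] <- TRUE; a_via[i] <- "n"
    }
  }

  rows <- list()
  for (i in seq_len(n_a)) {
    j <- a_partner[i]
    if (!is.na(j)) {
      nm <- identical(fa$product_name[i], fb$product_name[j])
      status <- if (a_via[i] == "c") "c_term_only" else "n_term_only"
      # perfect: both termini at equivalent positions, same matchSEG
      n_map <- map_term(ta$n_term[i]); c_map <- map_term(ta$c_term[i])
      both <- !is.na(n_map) && !is.na(c_map) &&
        n_map == tb$n_term[j] && c_map == tb$c_term[j]
      if (both) {
        seg_n <- posmap$a$seg[ta$n_term[i] + 1L]
        seg_c <- posmap$a$seg[ta$c_term[i] + 1L]
        if (seg_n == seg_c && nm) status <- "perfect"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        a_locus = fa$locus_tag[i], b_locus = fb$locus_tag[j],
        status = status, name_match = nm)
    } else {
      span <- (fa$start[i] + 1L):fa$end[i]
      status <- if (all(posmap$a$category[span] == "strain_specific"))
        "strain_specific" else "unmapped"
      rows[[length(rows) + 1L]] <- data.frame(
        a_locus = fa$locus_tag[i], b_locus = NA_character_,
        status = status, name_match = NA)
    }
  }
  for (j in which(!b_taken)) {
    span <- (fb$start[j] + 1L):fb$end[j]
    status <- if (all(posmap$b$category[span] == "strain_specific"))
      "strain_specific" else "unmapped"
    rows[[length(rows) + 1L]] <- data.frame(
      a_locus = NA_character_, b_locus = fb$locus_tag[j],
      status = status, name_match = NA)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a_locus = character(), b_locus = character(),
               status = character(), name_match = logical())
  rownames(out) <- NULL
  class(out) <- c("orf_correlation", "data.frame")
  out
}

# spliced CDS nucleotide sequence in reading orientation
cds_sequence <- function(genome, feature) {
  s <- substr0(genome$sequence, feature$start, feature$end)
  if (feature$strand == "-") s <- revcomp(s)
  s
}

translate_cds <- function(nt) {
  if (nchar(nt) %% 3L != 0L) return(NULL)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt),
    genetic.code = Biostrings::getGeneticCode(BACTERIAL_CODE),
    if.fuzzy.codon = "X"))
  aa
}

#' Verify protein identity of a correlated pair with start-codon reconciliation
#'
#' Returns TRUE when the two proteins are identical, or — for inconsistent
#' start-codon assignments — when the C-terminal fragments are identical for
#' the length of the shorter ORF. If the shorter ORF's assigned start codon
#' is GTG or TTG, the corresponding internal Val or Leu of the longer protein
#' is converted to Met before comparison; with an ATG start the fragments
#' must match as-is.
#'
#' @param a_nt,b_nt in-frame CDS nucleotide sequences (reading orientation).
#' @return TRUE/FALSE, or NA (with a warning) for untranslatable CDSs
#'   (length not a multiple of 3, or internal stop).
#' @export
verify_sequence_identity <- function(a_nt, b_nt) {
  pa <- translate_cds(a_nt); pb <- translate_cds(b_nt)
  if (is.null(pa) || is.null(pb)) {
    warning("CDS length not a multiple of 3; excluded from verification")
    return(NA)
  }
  pa <- sub("\\*$", "", pa); pb <- sub("\\*$", "", pb)
  if (grepl("\\*", pa) || grepl("\\*", pb)) {
    warning("internal stop codon; excluded from verification")
    return(NA)
  }
  if (nchar(pa) == nchar(pb)) return(identical(pa, pb))
  shorter_nt <- if (nchar(pa) < nchar(pb)) a_nt else b_nt
  long <- if (nchar(pa) < nchar(pb)) pb else pa
  short <- if (nchar(pa) < nchar(pb)) pa else pb
  offset <- nchar(long) - nchar(short)   # residues trimmed from the N-terminus
  frag <- substr(long, offset + 1L, nchar(long))
  start_codon <- toupper(substr(shorter_nt, 1L, 3L))
  if (start_codon %in% c("GTG", "TTG")) {
    # internal Val/Leu of the longer protein becomes the shorter's Met
    if (substr(frag, 1L, 1L) %in% c("V", "L")) {
      frag <- paste0("M", substr(frag, 2L, nchar(frag)))
    }
  }
  short_m <- if (start_codon %in% c("GTG", "TTG")) {
    paste0("M", substr(short, 2L, nchar(short)))
  } else short
  identical(frag, short_m)
}

#' Find genes regular in one strain and disrupted in the other
#'
#' A pair is reported when one genome carries a regular (non-pseudo) CDS
#' whose mapped span in the partner genome is annotated either as a
#' pseudo-flagged CDS or as a set of two or three ORFs (a split gene, e.g.
#' after a frameshift). Pairs pseudo-flagged on both sides are excluded.
#'
#' @param correlations result of [correlate_orfs()] (used to skip perfect pairs).
#' @param a,b annotated [genome_record()]s.
#' @param posmap the pair's `position_map`.
#' @param min_cover fraction of the partner ORF set's span that must fall
#'   inside the regular gene's mapped span.
#' @return data.frame: `regular_genome`, `regular_locus`, `partner_loci`,
#'   `kind` ("pseudo" or "split").
#' @export
find_disrupted <- function(correlations, a, b, posmap, min_cover = 0.5) {
  # pairs whose both sides are regular 1:1 correlations never match the
  # pseudo/split patterns below, so no perfect-pair pre-filter is needed;
  # a perfectly-positioned pair with a pseudo-flagged partner IS reported
  rows <- list()
  scan <- function(reg_genome, reg, part, reg_label, part_label, map_from, perfect_reg) {
    freg <- reg$features[reg$features$kind == "CDS" & !reg$features$pseudo, , drop = FALSE]
    fpart <- part$features[part$features$kind == "CDS", , drop = FALSE]
    for (i in seq_len(nrow(freg))) {
      span <- (freg$start[i] + 1L):freg$end[i]
      partner_pos <- posmap[[map_from]]$partner[span]
      partner_pos <- partner_pos[!is.na(partner_pos)]
      if (length(partner_pos) < 0.5 * length(span)) next
      lo <- min(partner_pos); hi <- max(partner_pos) + 1L
      inside <- which(fpart$start >= lo - 30L & fpart$end <= hi + 30L &
                        fpart$strand == freg$strand[i])
      if (length(inside) == 0L) next
      cover <- sum(fpart$end[inside] - fpart$start[inside]) / (hi - lo)
      if (length(inside) %in% 2:3 && cover >= min_cover) {
        rows[[length(rows) + 1L]] <<- data.frame(
          regular_genome = reg_label, regular_locus = freg$locus_tag[i],
          partner_loci = paste(fpart$locus_tag[inside], collapse = ";"),
          kind = "split")
      } else if (length(inside) == 1L && fpart$pseudo[inside]) {
        rows[[length(rows) + 1L]] <<- data.frame(
          regular_genome = reg_label, regular_locus = freg$locus_tag[i],
          partner_loci = fpart$locus_tag[inside], kind = "pseudo")
      }
    }
  }
  scan("a", a, b, "a", "b", "a", character())
  scan("b", b, a, "b", "a", "b", character())
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(regular_genome = character(), regular_locus = character(),
               partner_loci = character(), kind = character())
  rownames(out) <- NULL
  out
}

# best cross-proteome identity of one protein against a set, with a shared
# 5-mer prescreen before global alignment
best_proteome_identity <- function(query, proteome, params) {
  if (nchar(query) < 5L || length(proteome) == 0L) return(0)
  qk <- unique(substring(query, 1:(nchar(query) - 4L), 5:nchar(query)))
  best <- 0
  for (p in proteome) {
    if (nchar(p) < 5L) next
    pk <- substring(p, 1:(nchar(p) - 4L), 5:nchar(p))
    if (!any(pk %in% qk)) next
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(query), Biostrings::AAString(p), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5)
    id <- alignment_identity(list(
      a_aln = as.character(Biostrings::alignedPattern(pa)),
      b_aln = as.character(Biostrings::alignedSubject(pa))))
    if (!is.na(id) && id > best) best <- id
  }
  best
}

#' Filter strain-specific gene candidates
#'
#' Removes candidates with a close homolog (best cross-proteome global
#' alignment identity >= `min_homolog_identity`) in the other strain, and
#' candidates whose product name matches an exclusion keyword (mobile-element
#' and phage categories). Candidates shorter than `spurious_max_nt` with no
#' cross-proteome hit at all are re-rated `spurious_candidate`.
#'
#' @param correlations result of [correlate_orfs()].
#' @param a,b annotated [genome_record()]s.
#' @param min_homolog_identity homolog exclusion threshold (protein identity).
#' @param exclude_keywords product-name keywords excluded by category.
#' @param spurious_max_nt length bound for spurious-ORF rating (nucleotides).
#' @param params [align_params()] (unused placeholder for future scoring).
#' @return list with `a_specific`, `b_specific` (retained locus tags),
#'   `spurious` (locus tags re-rated), and `log` (per-candidate decisions).
#' @export
strain_specific_filter <- function(correlations, a, b,
                                   min_homolog_identity = 0.75,
                                   exclude_keywords = c("transposase", "integrase",
                                                        "phage", "prophage"),
                                   spurious_max_nt = 150L,
                                   params = align_params()) {
  get_protein <- function(genome, tag) {
    f <- genome$features[genome$features$locus_tag == tag, , drop = FALSE]
    p <- translate_cds(cds_sequence(genome, f[1L, ]))
    if (is.null(p)) NA_character_ else sub("\\*$", "", p)
  }
  proteome <- function(genome) {
    f <- genome$features[genome$features$kind == "CDS", , drop = FALSE]
    vapply(seq_len(nrow(f)), function(i) {
      p <- translate_cds(cds_sequence(genome, f[i, ]))
      if (is.null(p)) NA_character_ else sub("\\*$", "", p)
    }, "")
  }
  prot_a <- proteome(a); prot_b <- proteome(b)
  decide <- function(tags, self, other_proteome) {
    out <- data.frame(locus = character(), decision = character())
    retained <- character(); spurious <- character()
    for (tag in tags) {
      f <- self$features[self$features$locus_tag == tag, , drop = FALSE]
      kw <- any(vapply(exclude_keywords, grepl, TRUE,
                       x = tolower(f$product_name[1L]), fixed = TRUE))
      if (kw) {
        out <- rbind(out, data.frame(locus = tag, decision = "excluded_keyword"))
        next
      }
      p <- get_protein(self, tag)
      best <- if (is.na(p)) 0 else
        best_proteome_identity(p, other_proteome[!is.na(other_proteome)], params)
      if (best >= min_homolog_identity) {
        out <- rbind(out, data.frame(locus = tag, decision = "excluded_homolog"))
      } else if ((f$end[1L] - f$start[1L]) < spurious_max_nt && best == 0) {
        spurious <- c(spurious, tag)
        out <- rbind(out, data.frame(locus = tag, decision = "spurious_candidate"))
      } else {
        retained <- c(retained, tag)
        out <- rbind(out, data.frame(locus = tag, decision = "retained"))
      }
    }
    list(retained = retained, spurious = spurious, log = out)
  }
  ss <- correlations$status == "strain_specific"
  a_tags <- correlations$a_locus[ss & !is.na(correlations$a_locus)]
  b_tags <- correlations$b_locus[ss & !is.na(correlations$b_locus)]
  da <- decide(a_tags, a, prot_b)
  db <- decide(b_tags, b, prot_a)
  with_genome <- function(g, log) {
    if (nrow(log)) cbind(genome = g, log) else
      data.frame(genome = character(), locus = character(), decision = character())
  }
  list(a_specific = da$retained, b_specific = db$retained,
       spurious = c(da$spurious, db$spurious),
       log = rbind(with_genome("a", da$log), with_genome("b", db$log)))
}
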
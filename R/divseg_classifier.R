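# divseg_classifier: assign every divergent segment to one of four
# categories — tandem-repeat copy-number variation, indel, approximate
# insert, replacement — and tag inserts duplicated elsewhere in their own
# genome.

#' Detect a tandem-repeat unit in a sequence
#'
#' Scans unit lengths from `min_unit` to `max_unit` and reports the smallest
#' unit whose tandem tiling (allowing up to `max_mismatch_frac` mismatching
#' positions) covers at least `min_coverage` of the sequence. The unit is the
#' per-position majority base over the tiling; the copy count is the covered
#' length divided by the unit length, rounded down.
#'
#' @param s DNA string.
#' @param min_unit,max_unit unit length bounds in bp.
#' @param max_mismatch_frac tolerated fraction of mismatching positions.
#' @param min_coverage required fraction of `s` explained by the tiling.
#' @return `NULL`, or a list with `unit`, `unit_length`, `copies`,
#'   `mismatch_frac`.
#' @export
detect_tandem_unit <- function(s, min_unit = 7L, max_unit = 16L,
                               max_mismatch_frac = 0.10, min_coverage = 0.90) {
  if (!nzchar(s)) stop("sequence is empty", call. = FALSE)
  n <- nchar(s)
  chars <- strsplit(s, "", fixed = TRUE)[[1L]]
  for (u in min_unit:max_unit) {
    if (n < 2L * u) next
    # period-u self-similarity across the whole sequence
    lag_eq <- chars[seq_len(n - u)] == chars[(u + 1L):n]
    if (mean(lag_eq) < 1 - max_mismatch_frac) next
    # consensus unit over the tiling
    phase <- ((seq_len(n) - 1L) %% u) + 1L
    unit <- vapply(seq_len(u), function(p) {
      tb <- table(factor(chars[phase == p], levels = c("A", "C", "G", "T", "N")))
      names(tb)[which.max(tb)]   # ties resolved by fixed base order A<C<G<T
    }, "")
    tiled <- rep(unit, length.out = n)
    mismatch_frac <- mean(tiled != chars)
    if (mismatch_frac <= max_mismatch_frac && 1 - mismatch_frac >= min_coverage) {
      return(list(unit = paste(unit, collapse = ""), unit_length = u,
                  copies = n %/% u, mismatch_frac = mismatch_frac))
    }
  }
  NULL
}

#' Classify one divergent segment
#'
#' Decision order: tandem copy-number variation, indel, approximate insert,
#' replacement (the fallback). An indel has one exactly empty side;
#' an approximate insert tolerates up to `approx_tol` unaligned bases on the
#' other side; a replacement has dissimilar sequence on both sides and its
#' homology is measured by global alignment identity (a warning tag is added
#' at >= 95% identity, where the segment may belong in a matchSEG).
#'
#' @param a_side,b_side the divSEG sequences (either may be "").
#' @param a_genome,b_genome full genome sequences (flank context for tandem
#'   copy counting); optional but required to call tandem CNVs.
#' @param a_start,a_end,b_start,b_end the divSEG coordinates in the genomes.
#' @param approx_tol unaligned-base tolerance for approximate inserts (bp).
#' @param unit_range tandem unit length bounds.
#' @param params [align_params()] for replacement homology.
#' @return A list of class `divseg_call`: `category`, `carrier`,
#'   `homology_identity`, `unit`, `a_copies`, `b_copies`, `tags`.
#' @export
classify_divseg <- function(a_side, b_side, a_genome = NULL, b_genome = NULL,
                            a_start = NA, a_end = NA, b_start = NA, b_end = NA,
                            approx_tol = 10L, unit_range = c(7L, 16L),
                            params = align_params()) {
  la <- nchar(a_side); lb <- nchar(b_side)
  if (la == 0L && lb == 0L) stop("divSEG with both sides empty", call. = FALSE)
  call <- list(category = NA_character_, carrier = NA_character_,
               homology_identity = NA_real_, unit = NA_character_,
               a_copies = NA_integer_, b_copies = NA_integer_,
               tags = character())

  # (d) tandem copy-number variation
  if (!is.null(a_genome) && !is.null(b_genome) && max(la, lb) >= 2L * unit_range[1L]) {
    longer <- if (la >= lb) a_side else b_side
    hit <- detect_tandem_unit(longer, unit_range[1L], unit_range[2L])
    if (!is.null(hit)) {
      ca <- tandem_copies_at(a_genome, a_start, a_end, hit$unit)
      cb <- tandem_copies_at(b_genome, b_start, b_end, hit$unit)
      if (max(ca, cb) >= 2L && min(ca, cb) >= 1L && ca != cb) {
        call$category <- "tandem_cnv"
        call$unit <- hit$unit
        call$a_copies <- ca; call$b_copies <- cb
        call$carrier <- if (ca > cb) "a" else "b"
        return(structure(call, class = "divseg_call"))
      }
    }
  }
  # (a) indel: exactly one empty side
  if (la == 0L || lb == 0L) {
    call$category <- "indel"
    call$carrier <- if (la > 0L) "a" else "b"
    return(structure(call, class = "divseg_call"))
  }
  # (b) approximate insert: up to approx_tol unaligned bases on the short side
  if (min(la, lb) <= approx_tol) {
    call$category <- "approximate_insert"
    call$carrier <- if (la > lb) "a" else "b"
    return(structure(call, class = "divseg_call"))
  }
  # (c) replacement
  call$category <- "replacement"
  aln <- align_pair(a_side, b_side, params)
  call$homology_identity <- alignment_identity(aln)
  if (!is.na(call$homology_identity) && call$homology_identity >= 0.95) {
    call$tags <- c(call$tags, "HighIdentityReplacement")
  }
  structure(call, class = "divseg_call")
}

#' @export
print.divseg_call <- function(x, ...) {
  cat(sprintf("<divseg_call> %s%s%s\n", x$category,
              if (!is.na(x$carrier)) paste0(" in ", x$carrier) else "",
              if (length(x$tags)) paste0(" [", paste(x$tags, collapse = ","), "]") else ""))
  invisible(x)
}

# identity of a pairwise alignment: matches / aligned length excluding
# terminal gap columns
alignment_identity <- function(aln) {
  ra <- seq_as_raw(aln$a_aln); rb <- seq_as_raw(aln$b_aln)
  gap <- ra == RAW_GAP | rb == RAW_GAP
  inner <- which(!gap)
  if (length(inner) == 0L) return(NA_real_)
  span <- inner[1L]:inner[length(inner)]
  mean(ra[span] == rb[span] & !gap[span])
}

#' Tag an insert that is duplicated elsewhere in its own genome
#'
#' An insert is tagged `InternallyRepeated` when its sequence occurs at
#' another locus of the carrier genome at >= `min_identity` identity over
#' >= `min_length_frac` of its length (either strand).
#'
#' @param insert_seq the inserted sequence.
#' @param genome carrier genome sequence.
#' @param self_start,self_end the insert's own locus (excluded from the search).
#' @param min_identity,min_length_frac thresholds.
#' @return Character vector of tags (`"InternallyRepeated"` or empty).
#' @export
annotate_internal_repeats <- function(insert_seq, genome, self_start, self_end,
                                      min_identity = 0.90, min_length_frac = 0.80) {
  L <- nchar(insert_seq)
  if (L < 20L) return(character())
  core_len <- max(20L, ceiling(L * min_length_frac))
  off <- (L - core_len) %/% 2L
  core <- substr(insert_seq, off + 1L, off + core_len)
  # seed-and-verify: exact 16-mer seeds locate candidate loci, which are then
  # verified by alignment of the full core at the implied position
  k <- 16L
  if (core_len < k) return(character())
  seed_off <- seq(0L, core_len - k, by = k)
  subj <- Biostrings::DNAString(genome)
  n <- nchar(genome)
  for (strand in c("+", "-")) {
    pat_core <- if (strand == "+") core else revcomp(core)
    cand <- integer(0)
    for (so in seed_off) {
      seed <- substr(pat_core, so + 1L, so + k)
      hits <- Biostrings::matchPattern(Biostrings::DNAString(seed), subj)
      st <- BiocGenerics::start(hits) - 1L
      cand <- c(cand, st - so)                 # implied core start
    }
    cand <- cand[cand >= 0L & cand + core_len <= n]
    cand <- unique(round(cand / 20) * 20)      # cluster nearby implied starts
    for (cs in cand) {
      lo <- max(0L, cs - 20L); hi <- min(n, cs + core_len + 20L)
      if (lo >= self_start - core_len && hi <= self_end + core_len &&
          hi > self_start && lo < self_end) next   # the insert's own locus
      window <- substr0(genome, lo, hi)
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(pat_core), Biostrings::DNAString(window),
        type = "global-local")
      id <- alignment_identity(list(
        a_aln = as.character(Biostrings::alignedPattern(pa)),
        b_aln = as.character(Biostrings::alignedSubject(pa))))
      if (!is.na(id) && id >= min_identity) return("InternallyRepeated")
    }
  }
  character()
}

#' Classify every divSEG of a segmentation
#'
#' Runs [classify_divseg()] over all divergent segments of a finished
#' segmentation and, for indels and approximate inserts, applies
#' [annotate_internal_repeats()] to the carried sequence.
#'
#' @param seg a `pairseg_segmentation` (must carry its genome sequences, as
#'   produced by [compare_genomes()] / [extract_segments()]).
#' @param approx_tol,unit_range,params see [classify_divseg()].
#' @param tag_repeats logical; search the carrier genome for internal
#'   duplications of each insert.
#' @return data.frame: `seg_row` (row in [segment_table()]), coordinates,
#'   `category`, `carrier`, `unit`, `a_copies`, `b_copies`,
#'   `homology_identity`, `tags`.
#' @export
classify_divsegs <- function(seg, approx_tol = 10L, unit_range = c(7L, 16L),
                             params = align_params(), tag_repeats = TRUE) {
  stopifnot(inherits(seg, "pairseg_segmentation"))
  tab <- segment_table(seg)
  idx <- which(tab$type == "div")
  rows <- lapply(idx, function(r) {
    row <- tab[r, ]
    a_side <- substr0(seg$a_seq, row$a_start, row$a_end)
    b_side <- substr0(seg$b_seq, row$b_start, row$b_end)
    call <- classify_divseg(a_side, b_side, seg$a_seq, seg$b_seq,
                            row$a_start, row$a_end, row$b_start, row$b_end,
                            approx_tol = approx_tol, unit_range = unit_range,
                            params = params)
    tags <- call$tags
    if (tag_repeats && call$category %in% c("indel", "approximate_insert")) {
      ins <- if (call$carrier == "a") a_side else b_side
      gen <- if (call$carrier == "a") seg$a_seq else seg$b_seq
      ss <- if (call$carrier == "a") row$a_start else row$b_start
      se <- if (call$carrier == "a") row$a_end else row$b_end
      tags <- c(tags, annotate_internal_repeats(ins, gen, ss, se))
    }
    data.frame(seg_row = r, a_start = row$a_start, a_end = row$a_end,
               b_start = row$b_start, b_end = row$b_end,
               category = call$category, carrier = call$carrier,
               unit = call$unit, a_copies = call$a_copies,
               b_copies = call$b_copies,
               homology_identity = call$homology_identity,
               tags = paste(tags, collapse = ";"))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seg_row = integer(), a_start = integer(), a_end = integer(),
               b_start = integer(), b_end = integer(), category = character(),
               carrier = character(), unit = character(),
               a_copies = integer(), b_copies = integer(),
               homology_identity = numeric(), tags = character())
  rownames(out) <- NULL
  out
}
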
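# segmenter: three-pass segmentation of two moderately diverged, colinear
# genomes into matching segments (matchSEGs) and divergent segments (divSEGs).
#
# Pass 1 (first_pass) traverses both chromosomes in 200 kb chunks, each chunk
# restarting at the beginning of the last matching stretch of the previous
# one. Pass 2 (extract_segments) cuts the chunk alignments into matchSEGs at
# indels longer than `max_indel` and at windows of elevated divergence, and
# trims every matchSEG so it starts and ends on a matching base. Pass 3
# (refine) splits matchSEGs containing long internal indels, fuses matchSEGs
# separated by less than `fuse_below` bases in both genomes, re-aligns and
# recomputes statistics, and flags matchSEGs above 1% divergence for review.

#' First pass: chunked traversal of two genomes
#'
#' Compares the genomes in chunks of `chunk` bases. For each chunk both
#' sequences are decomposed into runs and connectors, the connectors are
#' aligned, and the alignment up to the start of the last matching stretch is
#' emitted; the next chunk restarts at that stretch. When the last matching
#' stretch would give less than a quarter-chunk of progress (e.g. a fully
#' identical chunk), the restart point moves to 200 bases before the end of
#' that stretch instead, so the traversal always advances. Emitted chunk
#' alignments tile both genomes completely.
#'
#' @param a,b [genome_record()]s or DNA strings.
#' @param chunk chunk size in bases.
#' @param params [align_params()].
#' @return A list of class `pairseg_chunks`: per chunk `a_from`, `b_from`,
#'   `a_to`, `b_to` (emitted interval, 0-based half-open), `a_aln`, `b_aln`,
#'   and `restart_a`, `restart_b` (absolute restart coordinates, NA for the
#'   final chunk).
#' @export
first_pass <- function(a, b, chunk = 200000L, params = align_params()) {
  sa <- genome_seq(a); sb <- genome_seq(b)
  na <- nchar(sa); nb <- nchar(sb)
  ai <- 0L; bi <- 0L
  chunks <- list()
  repeat {
    a_to <- min(ai + chunk, na); b_to <- min(bi + chunk, nb)
    at_end <- (a_to == na && b_to == nb)
    sub_a <- substr0(sa, ai, a_to); sub_b <- substr0(sb, bi, b_to)
    dec <- decompose(sub_a, sub_b, min_run = params$min_run)
    runs <- dec[dec$type == "run", , drop = FALSE]
    if (at_end || nrow(runs) == 0L) {
      aln <- stitch_from_dec(dec, sub_a, sub_b, params)
      chunks[[length(chunks) + 1L]] <- list(
        a_from = ai, b_from = bi, a_to = a_to, b_to = b_to,
        a_aln = aln$a_aln, b_aln = aln$b_aln,
        restart_a = NA_integer_, restart_b = NA_integer_)
      if (at_end) break
      ai <- a_to; bi <- b_to
      next
    }
    last <- runs[nrow(runs), ]
    restart_a <- last$a_start; restart_b <- last$b_start
    if (restart_a < chunk %/% 4L) {
      off <- max(0L, (last$a_end - last$a_start) - 200L)
      restart_a <- last$a_start + off
      restart_b <- last$b_start + off
    }
    if (restart_a <= 0L) {  # degenerate tiny chunk: emit everything
      aln <- stitch_from_dec(dec, sub_a, sub_b, params)
      chunks[[length(chunks) + 1L]] <- list(
        a_from = ai, b_from = bi, a_to = a_to, b_to = b_to,
        a_aln = aln$a_aln, b_aln = aln$b_aln,
        restart_a = NA_integer_, restart_b = NA_integer_)
      ai <- a_to; bi <- b_to
      if (ai >= na && bi >= nb) break
      next
    }
    aln <- stitch_from_dec(dec, sub_a, sub_b, params,
                           a_limit = restart_a, b_limit = restart_b)
    chunks[[length(chunks) + 1L]] <- list(
      a_from = ai, b_from = bi, a_to = ai + restart_a, b_to = bi + restart_b,
      a_aln = aln$a_aln, b_aln = aln$b_aln,
      restart_a = ai + restart_a, restart_b = bi + restart_b)
    ai <- ai + restart_a; bi <- bi + restart_b
  }
  structure(chunks, class = "pairseg_chunks",
            a_len = na, b_len = nb,
            a_id = if (inherits(a, "genome_record")) a$id else "a",
            b_id = if (inherits(b, "genome_record")) b$id else "b")
}

#' Second pass: extract matchSEGs and divSEGs from the chunk alignments
#'
#' Concatenates the emitted chunk alignments into one genome-wide alignment,
#' then cuts it into matchSEGs wherever an indel longer than `max_indel`
#' bases occurs or a sliding window of `window` alignment columns exceeds
#' `max_window_div` divergence. Each matchSEG is trimmed to start and end on
#' a matching base; everything between matchSEGs becomes a divSEG.
#'
#' @param chunks a `pairseg_chunks` object from [first_pass()].
#' @param max_indel maximum internal indel length tolerated inside a matchSEG.
#' @param window,max_window_div sliding-window rule that terminates a
#'   matchSEG on a significant increase in sequence dissimilarity.
#' @param params [align_params()] used later by [refine()].
#' @return A `pairseg_segmentation` object; see [segment_table()].
#' @export
extract_segments <- function(chunks, max_indel = 100L, window = 1000L,
                             max_window_div = 0.05, params = align_params()) {
  stopifnot(inherits(chunks, "pairseg_chunks"))
  a_aln <- paste(vapply(chunks, `[[`, "", "a_aln"), collapse = "")
  b_aln <- paste(vapply(chunks, `[[`, "", "b_aln"), collapse = "")
  seg <- segment_alignment(a_aln, b_aln, max_indel, window, max_window_div)
  structure(list(match = seg,
                 a_seq = gsub("-", "", a_aln, fixed = TRUE),
                 b_seq = gsub("-", "", b_aln, fixed = TRUE),
                 a_len = attr(chunks, "a_len"), b_len = attr(chunks, "b_len"),
                 a_id = attr(chunks, "a_id"), b_id = attr(chunks, "b_id"),
                 max_indel = as.integer(max_indel), window = as.integer(window),
                 max_window_div = max_window_div, params = params),
            class = "pairseg_segmentation")
}

# cut one genome-wide alignment into matchSEG rows (with per-segment
# alignments and column stats); returns a data.frame with an `alignments`
# attribute parallel to its rows
segment_alignment <- function(a_aln, b_aln, max_indel, window, max_window_div) {
  ra <- seq_as_raw(a_aln); rb <- seq_as_raw(b_aln)
  nc <- length(ra)
  gapA <- ra == RAW_GAP; gapB <- rb == RAW_GAP
  eq <- !gapA & !gapB & ra == rb & ra != RAW_N
  mm <- !gapA & !gapB & !eq

  divider <- long_gap_mask(gapA, max_indel) | long_gap_mask(gapB, max_indel)
  divider <- divider | window_divergence_mask(gapA, gapB, mm, window, max_window_div)

  # candidate matchSEG column intervals, trimmed to matching bases
  r <- rle(as.vector(!divider))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  iv <- cbind(starts, ends)[r$values, , drop = FALSE]
  rows <- list(); alns <- list()
  cntA <- cumsum(!gapA); cntB <- cumsum(!gapB)
  for (i in seq_len(nrow(iv))) {
    s <- iv[i, 1L]; e <- iv[i, 2L]
    hits <- which(eq[s:e])
    if (length(hits) == 0L) next
    s2 <- s + hits[1L] - 1L
    e2 <- s + hits[length(hits)] - 1L
    a_sub <- rawToChar(ra[s2:e2]); b_sub <- rawToChar(rb[s2:e2])
    cs <- classify_columns(a_sub, b_sub)
    rows[[length(rows) + 1L]] <- data.frame(
      a_start = if (s2 > 1L) cntA[s2 - 1L] else 0L,
      a_end = cntA[e2],
      b_start = if (s2 > 1L) cntB[s2 - 1L] else 0L,
      b_end = cntB[e2],
      m = cs$m, mm = cs$mm, go = cs$go, ge = cs$ge,
      divergence = divergence(cs))
    alns[[length(rows)]] <- list(a_aln = a_sub, b_aln = b_sub)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a_start = integer(), a_end = integer(), b_start = integer(),
               b_end = integer(), m = integer(), mm = integer(),
               go = integer(), ge = integer(), divergence = numeric())
  rownames(out) <- NULL
  attr(out, "alignments") <- alns
  out
}

long_gap_mask <- function(gap, max_indel) {
  r <- rle(as.vector(gap))
  r$values <- r$values & r$lengths > max_indel
  inverse.rle(r)
}

# columns covered by any window of `window` informative (m/mm/go) columns
# whose divergence (mm + go) / (m + mm + go) exceeds the threshold;
# gap-extension columns carry no information and are skipped by the window
window_divergence_mask <- function(gapA, gapB, mm, window, max_window_div) {
  nc <- length(mm)
  go <- gap_open_cols(gapA) | gap_open_cols(gapB)
  ge <- (gapA | gapB) & !go
  idx <- which(!ge)
  ni <- length(idx)
  w <- min(window, ni)
  if (w < 10L) return(rep(FALSE, nc))
  d <- as.integer(mm[idx] | go[idx])
  D <- c(0L, cumsum(d))
  s <- seq_len(ni - w + 1L)
  bad <- (D[s + w] - D[s]) / w > max_window_div
  if (!any(bad)) return(rep(FALSE, nc))
  out <- rep(FALSE, nc)
  bs <- s[bad]
  # mark the full span of each exceeding window (in original columns)
  from <- idx[bs]; to <- idx[bs + w - 1L]
  delta <- integer(nc + 1L)
  for (k in seq_along(from)) {
    delta[from[k]] <- delta[from[k]] + 1L
    delta[to[k] + 1L] <- delta[to[k] + 1L] - 1L
  }
  cumsum(delta[seq_len(nc)]) > 0L
}

# first column of every maximal gap run in one alignment row
gap_open_cols <- function(gap) {
  out <- gap & !c(FALSE, gap[-length(gap)])
  out
}

#' Third pass: refine a draft segmentation
#'
#' Splits matchSEGs whose alignment contains an internal indel longer than
#' `max_indel`, fuses matchSEGs separated by less than `fuse_below` bases in
#' both genomes (re-aligning the fused span and recomputing statistics), and
#' iterates to a fixed point. matchSEGs with more than 1% divergence are
#' retained but flagged (attribute `flagged`). The partition invariant is
#' re-verified on exit.
#'
#' @param x a `pairseg_segmentation`.
#' @param fuse_below fuse matchSEGs closer than this in both genomes.
#' @param max_indel split threshold for internal indels.
#' @return The refined `pairseg_segmentation`.
#' @export
refine <- function(x, fuse_below = 100L, max_indel = NULL) {
  stopifnot(inherits(x, "pairseg_segmentation"))
  if (is.null(max_indel)) max_indel <- x$max_indel
  for (iter in seq_len(20L)) {
    changed <- FALSE
    sp <- refine_split(x, max_indel)
    x <- sp$x; changed <- changed || sp$changed
    fu <- refine_fuse(x, fuse_below, max_indel)
    x <- fu$x; changed <- changed || fu$changed
    if (!changed) break
  }
  check_partition(x)
  attr(x$match, "flagged") <- which(x$match$divergence > 0.01)
  x
}

refine_split <- function(x, max_indel) {
  m <- x$match; alns <- attr(m, "alignments")
  new_rows <- list(); new_alns <- list(); changed <- FALSE
  for (i in seq_len(nrow(m))) {
    seg <- segment_alignment(alns[[i]]$a_aln, alns[[i]]$b_aln, max_indel,
                             x$window, x$max_window_div)
    if (nrow(seg) == 1L) {
      piece <- seg[1L, ]
      piece$a_start <- piece$a_start + m$a_start[i]
      piece$a_end <- piece$a_end + m$a_start[i]
      piece$b_start <- piece$b_start + m$b_start[i]
      piece$b_end <- piece$b_end + m$b_start[i]
      new_rows[[length(new_rows) + 1L]] <- piece
      new_alns[[length(new_rows)]] <- attr(seg, "alignments")[[1L]]
    } else {
      changed <- TRUE
      sub_alns <- attr(seg, "alignments")
      for (j in seq_len(nrow(seg))) {
        piece <- seg[j, ]
        piece$a_start <- piece$a_start + m$a_start[i]
        piece$a_end <- piece$a_end + m$a_start[i]
        piece$b_start <- piece$b_start + m$b_start[i]
        piece$b_end <- piece$b_end + m$b_start[i]
        new_rows[[length(new_rows) + 1L]] <- piece
        new_alns[[length(new_rows)]] <- sub_alns[[j]]
      }
    }
  }
  m2 <- if (length(new_rows)) do.call(rbind, new_rows) else m[0L, ]
  rownames(m2) <- NULL
  attr(m2, "alignments") <- new_alns
  x$match <- m2
  list(x = x, changed = changed)
}

refine_fuse <- function(x, fuse_below, max_indel) {
  m <- x$match; alns <- attr(m, "alignments")
  if (nrow(m) <= 1L) return(list(x = x, changed = FALSE))
  changed <- FALSE
  i <- 1L
  while (i < nrow(m)) {
    gap_a <- m$a_start[i + 1L] - m$a_end[i]
    gap_b <- m$b_start[i + 1L] - m$b_end[i]
    if (gap_a < fuse_below && gap_b < fuse_below) {
      aln <- align_pair(substr0(x$a_seq, m$a_start[i], m$a_end[i + 1L]),
                        substr0(x$b_seq, m$b_start[i], m$b_end[i + 1L]),
                        x$params)
      cs <- classify_columns(aln$a_aln, aln$b_aln)
      m$a_end[i] <- m$a_end[i + 1L]; m$b_end[i] <- m$b_end[i + 1L]
      m$m[i] <- cs$m; m$mm[i] <- cs$mm; m$go[i] <- cs$go; m$ge[i] <- cs$ge
      m$divergence[i] <- divergence(cs)
      alns[[i]] <- list(a_aln = aln$a_aln, b_aln = aln$b_aln)
      m <- m[-(i + 1L), , drop = FALSE]
      alns[[i + 1L]] <- NULL
      rownames(m) <- NULL
      changed <- TRUE
    } else {
      i <- i + 1L
    }
  }
  attr(m, "alignments") <- alns
  x$match <- m
  list(x = x, changed = changed)
}

check_partition <- function(x) {
  m <- x$match
  if (nrow(m) == 0L) return(invisible(TRUE))
  if (is.unsorted(m$a_start) || is.unsorted(m$b_start)) {
    stop("segmentation is not ordered", call. = FALSE)
  }
  if (any(m$a_start[-1L] < m$a_end[-nrow(m)]) ||
      any(m$b_start[-1L] < m$b_end[-nrow(m)])) {
    stop("matchSEG intervals overlap: partition violated", call. = FALSE)
  }
  if (any(m$a_end > x$a_len) || any(m$b_end > x$b_len)) {
    stop("matchSEG exceeds genome bounds", call. = FALSE)
  }
  invisible(TRUE)
}

#' Full ordered segment table of a segmentation
#'
#' Expands a segmentation into the exhaustive alternating list of matchSEGs
#' and divSEGs: every position of each genome belongs to exactly one row.
#' DivSEG rows have NA column statistics (they are classified separately by
#' [classify_divsegs()]).
#'
#' @param x a `pairseg_segmentation`.
#' @return A data.frame with columns `type` ("match"/"div"), `a_start`,
#'   `a_end`, `b_start`, `b_end`, `m`, `mm`, `go`, `ge`, `divergence`.
#' @export
segment_table <- function(x) {
  stopifnot(inherits(x, "pairseg_segmentation"))
  m <- x$match
  rows <- list()
  ca <- 0L; cb <- 0L
  div_row <- function(as_, ae, bs, be) {
    data.frame(type = "div", a_start = as_, a_end = ae, b_start = bs, b_end = be,
               m = NA_integer_, mm = NA_integer_, go = NA_integer_,
               ge = NA_integer_, divergence = NA_real_)
  }
  for (i in seq_len(nrow(m))) {
    if (m$a_start[i] > ca || m$b_start[i] > cb) {
      rows[[length(rows) + 1L]] <- div_row(ca, m$a_start[i], cb, m$b_start[i])
    }
    rows[[length(rows) + 1L]] <- cbind(data.frame(type = "match"),
                                       m[i, , drop = FALSE])
    ca <- m$a_end[i]; cb <- m$b_end[i]
  }
  if (ca < x$a_len || cb < x$b_len) {
    rows[[length(rows) + 1L]] <- div_row(ca, x$a_len, cb, x$b_len)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    div_row(0L, x$a_len, 0L, x$b_len)
  rownames(out) <- NULL
  out
}

#' @export
print.pairseg_segmentation <- function(x, ...) {
  tab <- segment_table(x)
  nm <- sum(tab$type == "match"); nd <- sum(tab$type == "div")
  cat(sprintf("<pairseg_segmentation> %s (%s bp) vs %s (%s bp): %d matchSEG(s), %d divSEG(s)\n",
              x$a_id, format(x$a_len, big.mark = ","),
              x$b_id, format(x$b_len, big.mark = ","), nm, nd))
  if (nm > 0) {
    cs <- segmentation_stats(x)
    cat(sprintf("  cumulative identity %.4f; matchSEG coverage a %.1f%%, b %.1f%%\n",
                cs$cumulative_identity, 100 * cs$a_match_coverage,
                100 * cs$b_match_coverage))
  }
  invisible(x)
}

#' Genome-wide summary statistics of a segmentation
#'
#' Cumulative statistics are computed by summing the m/mm/go/ge counts across
#' matchSEGs, not by averaging per-segment fractions.
#'
#' @param x a `pairseg_segmentation`.
#' @return A list: segment counts, per-genome matchSEG coverage fractions,
#'   cumulative identity and divergence, total point mutations (mismatch
#'   columns) and one-base indels within matchSEGs, and total divSEG bases
#'   per genome.
#' @export
segmentation_stats <- function(x) {
  stopifnot(inherits(x, "pairseg_segmentation"))
  m <- x$match
  tab <- segment_table(x)
  div <- tab[tab$type == "div", , drop = FALSE]
  alns <- attr(m, "alignments")
  one_base <- 0L
  for (al in alns) {
    for (row in c("a_aln", "b_aln")) {
      r <- rle(as.vector(seq_as_raw(al[[row]]) == RAW_GAP))
      one_base <- one_base + sum(r$values & r$lengths == 1L)
    }
  }
  tot <- list(m = sum(m$m), mm = sum(m$mm), go = sum(m$go), ge = sum(m$ge))
  denom <- tot$m + tot$mm + tot$go
  list(
    n_matchseg = nrow(m),
    n_divseg = nrow(div),
    a_match_coverage = sum(m$a_end - m$a_start) / x$a_len,
    b_match_coverage = sum(m$b_end - m$b_start) / x$b_len,
    cumulative_identity = if (denom > 0) tot$m / denom else NA_real_,
    cumulative_divergence = if (denom > 0) (tot$mm + tot$go) / denom else NA_real_,
    n_point_mutations = tot$mm,
    n_one_base_indels = one_base,
    a_div_bases = sum(div$a_end - div$a_start),
    b_div_bases = sum(div$b_end - div$b_start)
  )
}

#' Compare two genomes end to end
#'
#' Runs the three passes — [first_pass()], [extract_segments()], [refine()] —
#' and returns the final segmentation.
#'
#' @inheritParams first_pass
#' @inheritParams extract_segments
#' @param fuse_below fuse threshold for pass 3.
#' @return A `pairseg_segmentation`.
#' @export
compare_genomes <- function(a, b, chunk = 200000L, max_indel = 100L,
                            window = 1000L, max_window_div = 0.05,
                            fuse_below = 100L, params = align_params()) {
  chunks <- first_pass(a, b, chunk = chunk, params = params)
  draft <- extract_segments(chunks, max_indel = max_indel, window = window,
                            max_window_div = max_window_div, params = params)
  refine(draft, fuse_below = fuse_below, max_indel = max_indel)
}
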
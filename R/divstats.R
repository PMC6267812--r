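# divstats: alignment column classification, the divergence statistic, and
# per-base position-correlation maps between the two genomes.

#' Classify the columns of a pairwise alignment
#'
#' Every column is assigned exactly one class: match (`m`), mismatch (`mm`),
#' gap open (`go`) or gap extension (`ge`). The first column of every maximal
#' gap run in either row is the run's single `go`; its remaining columns are
#' `ge`. A column containing `N` in either row counts as a mismatch.
#'
#' @param a_aln,b_aln equal-length gapped strings, or a `pairwise_alignment`
#'   as the first argument.
#' @return A list of class `column_stats` with counts `m`, `mm`, `go`, `ge`
#'   summing to the alignment length.
#' @export
classify_columns <- function(a_aln, b_aln = NULL) {
  if (inherits(a_aln, "pairwise_alignment")) {
    b_aln <- a_aln$b_aln; a_aln <- a_aln$a_aln
  }
  if (nchar(a_aln) != nchar(b_aln)) {
    stop("aligned strings must have equal length", call. = FALSE)
  }
  ra <- seq_as_raw(a_aln); rb <- seq_as_raw(b_aln)
  gapA <- ra == RAW_GAP; gapB <- rb == RAW_GAP
  if (any(gapA & gapB)) stop("column gapped in both rows", call. = FALSE)
  eq <- !gapA & !gapB & ra == rb & ra != RAW_N & rb != RAW_N
  mm <- !gapA & !gapB & !eq
  go <- gap_open_cols(gapA) | gap_open_cols(gapB)
  ge <- (gapA | gapB) & !go
  structure(list(m = sum(eq), mm = sum(mm), go = sum(go), ge = sum(ge)),
            class = "column_stats")
}

#' @export
print.column_stats <- function(x, ...) {
  cat(sprintf("<column_stats> m=%d mm=%d go=%d ge=%d (divergence %.4f)\n",
              x$m, x$mm, x$go, x$ge, divergence(x)))
  invisible(x)
}

#' Sequence divergence of an alignment
#'
#' The divergence of a set of classified columns is
#' `(mm + go) / (m + mm + go)`: gap-extension columns are excluded entirely,
#' and each gap contributes a single gap-open event.
#'
#' @param stats a `column_stats` list (or anything with `m`, `mm`, `go`).
#' @return Divergence fraction in `[0, 1]`.
#' @export
divergence <- function(stats) {
  denom <- stats$m + stats$mm + stats$go
  if (denom == 0) {
    stop("divergence undefined: no m/mm/go columns", call. = FALSE)
  }
  (stats$mm + stats$go) / denom
}

#' Build the per-base position-correlation map of a segmentation
#'
#' Classifies every position of each genome as `mapped` (within a matchSEG
#' and aligned to a base of the other genome; the partner coordinate is
#' recorded), `gap` (within a matchSEG but opposite an alignment gap), or
#' `strain_specific` (within a divSEG). The mapped relation is a strictly
#' increasing partial bijection between the genomes.
#'
#' @param seg a `pairseg_segmentation`.
#' @return An object of class `position_map`: for each genome a list with
#'   `category` (factor: mapped/gap/strain_specific), `partner` (0-based
#'   coordinate in the other genome, NA unless mapped) and `seg` (row index
#'   into [segment_table()]).
#' @export
build_position_map <- function(seg) {
  stopifnot(inherits(seg, "pairseg_segmentation"))
  tab <- segment_table(seg)
  lv <- c("mapped", "gap", "strain_specific")
  a_cat <- integer(seg$a_len); a_par <- rep(NA_integer_, seg$a_len)
  b_cat <- integer(seg$b_len); b_par <- rep(NA_integer_, seg$b_len)
  a_seg <- integer(seg$a_len); b_seg <- integer(seg$b_len)
  alns <- attr(seg$match, "alignments")
  mi <- 0L
  for (r in seq_len(nrow(tab))) {
    row <- tab[r, ]
    if (row$type == "div") {
      if (row$a_end > row$a_start) {
        a_cat[(row$a_start + 1L):row$a_end] <- 3L
        a_seg[(row$a_start + 1L):row$a_end] <- r
      }
      if (row$b_end > row$b_start) {
        b_cat[(row$b_start + 1L):row$b_end] <- 3L
        b_seg[(row$b_start + 1L):row$b_end] <- r
      }
      next
    }
    mi <- mi + 1L
    al <- alns[[mi]]
    ra <- seq_as_raw(al$a_aln); rb <- seq_as_raw(al$b_aln)
    gapA <- ra == RAW_GAP; gapB <- rb == RAW_GAP
    apos <- row$a_start + cumsum(!gapA)   # 1-based genome position per column
    bpos <- row$b_start + cumsum(!gapB)
    both <- !gapA & !gapB
    a_cat[apos[both]] <- 1L; a_par[apos[both]] <- bpos[both] - 1L
    b_cat[bpos[both]] <- 1L; b_par[bpos[both]] <- apos[both] - 1L
    a_only <- !gapA & gapB
    b_only <- gapA & !gapB
    a_cat[apos[a_only]] <- 2L
    b_cat[bpos[b_only]] <- 2L
    a_seg[(row$a_start + 1L):row$a_end] <- r
    b_seg[(row$b_start + 1L):row$b_end] <- r
  }
  if (any(a_cat == 0L) || any(b_cat == 0L)) {
    stop("segmentation does not partition the genomes", call. = FALSE)
  }
  structure(list(
    a = list(category = factor(lv[a_cat], levels = lv), partner = a_par, seg = a_seg),
    b = list(category = factor(lv[b_cat], levels = lv), partner = b_par, seg = b_seg),
    a_len = seg$a_len, b_len = seg$b_len,
    segments = tab), class = "position_map")
}

#' @export
print.position_map <- function(x, ...) {
  cat("<position_map>\n")
  for (g in c("a", "b")) {
    tb <- table(x[[g]]$category)
    cat(sprintf("  genome %s: %d mapped, %d gap, %d strain-specific\n",
                g, tb[["mapped"]], tb[["gap"]], tb[["strain_specific"]]))
  }
  invisible(x)
}

#' Map a coordinate through a position map
#'
#' @param posmap a `position_map`.
#' @param pos 0-based position(s).
#' @param from `"a"` or `"b"`: the genome `pos` refers to.
#' @return 0-based partner coordinates (NA where not mapped).
#' @export
map_position <- function(posmap, pos, from = c("a", "b")) {
  from <- match.arg(from)
  posmap[[from]]$partner[pos + 1L]
}

#' Export a position map as a coordinate liftover table
#'
#' @param posmap a `position_map`.
#' @return data.frame with 0-based `pos_a`, `pos_b` for all mapped positions.
#' @export
position_map_table <- function(posmap) {
  mapped <- which(posmap$a$category == "mapped") - 1L
  data.frame(pos_a = mapped, pos_b = posmap$a$partner[mapped + 1L])
}

#' Strain-specific intervals of one genome as a BED-style table
#'
#' @param posmap a `position_map`.
#' @param genome `"a"` or `"b"`.
#' @param seqid sequence name for the BED `seqid` column.
#' @return data.frame with `seqid`, 0-based half-open `start`, `end`.
#' @export
strain_specific_intervals <- function(posmap, genome = c("a", "b"), seqid = genome) {
  genome <- match.arg(genome)
  ss <- posmap[[genome]]$category == "strain_specific"
  r <- rle(as.vector(ss))
  ends <- cumsum(r$lengths); starts <- ends - r$lengths
  keep <- r$values
  data.frame(seqid = rep(seqid[1L], sum(keep)),
             start = starts[keep], end = ends[keep])
}
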
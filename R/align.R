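# Pairwise alignment engine behind the segmenter. Small inputs get a full
# affine-gap dynamic program (Biostrings); large near-identical inputs are
# anchored on the run/connector decomposition and only the connectors are
# aligned by DP, which keeps whole-chromosome comparisons tractable.

#' Alignment parameters
#'
#' Affine-gap scoring: a gap of length L costs `gap_open + gap_ext * L`.
#' `exact_cells` caps the DP matrix size (rows x columns) for the exact
#' aligner; larger problems are anchored on exact matches, and connectors
#' that still exceed the cap are emitted as two adjacent gap blocks.
#'
#' @param match,mismatch,gap_open,gap_ext scoring (penalties positive).
#' @param exact_cells DP matrix cell budget for the exact route.
#' @param min_run anchor size for the anchored route.
#' @return A list of parameters.
#' @export
align_params <- function(match = 1, mismatch = -2, gap_open = 4, gap_ext = 1,
                         exact_cells = 1e7, min_run = 20L) {
  list(match = match, mismatch = mismatch, gap_open = gap_open,
       gap_ext = gap_ext, exact_cells = exact_cells, min_run = as.integer(min_run))
}

#' Globally align two DNA strings
#'
#' Returns a pairwise alignment: two equal-length gapped strings from which
#' removing the gaps restores the inputs. Optimal under the affine scheme for
#' inputs within the DP cell budget; near-optimal (anchored) beyond it.
#' Deterministic for fixed inputs and parameters.
#'
#' @param a,b DNA strings.
#' @param params an [align_params()] list.
#' @return An object of class `pairwise_alignment`: list with `a_aln`,
#'   `b_aln` and `score` (scored uniformly by [alignment_score()]).
#' @export
align_pair <- function(a, b, params = align_params()) {
  a <- genome_seq(a); b <- genome_seq(b)
  if (nchar(a) == 0L || nchar(b) == 0L) {
    stop("align_pair needs two non-empty sequences", call. = FALSE)
  }
  aln <- if (as.numeric(nchar(a)) * nchar(b) <= params$exact_cells) {
    dp_align(a, b, params)
  } else {
    anchored_align(a, b, params)
  }
  new_alignment(aln$a_aln, aln$b_aln, params)
}

new_alignment <- function(a_aln, b_aln, params = align_params()) {
  stopifnot(nchar(a_aln) == nchar(b_aln))
  structure(list(a_aln = a_aln, b_aln = b_aln,
                 score = alignment_score(a_aln, b_aln, params)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %d columns, score %.1f\n",
              nchar(x$a_aln), x$score))
  invisible(x)
}

#' Score a gapped alignment under the affine scheme
#'
#' @param a_aln,b_aln equal-length gapped strings.
#' @param params an [align_params()] list.
#' @return The numeric score.
#' @export
alignment_score <- function(a_aln, b_aln, params = align_params()) {
  cs <- classify_columns(a_aln, b_aln)
  n_gap_runs <- cs$go
  gap_bases <- cs$go + cs$ge
  cs$m * params$match + cs$mm * params$mismatch -
    n_gap_runs * params$gap_open - gap_bases * params$gap_ext
}

dp_align <- function(a, b, params) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = mat, gapOpening = params$gap_open,
    gapExtension = params$gap_ext)
  list(a_aln = as.character(Biostrings::alignedPattern(pa)),
       b_aln = as.character(Biostrings::alignedSubject(pa)))
}

anchored_align <- function(a, b, params) {
  dec <- decompose(a, b, min_run = params$min_run)
  stitch_from_dec(dec, a, b, params)
}

# build the gapped strings for a decomposition, optionally truncated at the
# local coordinates (a_limit, b_limit), which must sit at or inside a run
stitch_from_dec <- function(dec, a, b, params, a_limit = NULL, b_limit = NULL) {
  pieces_a <- character(0)
  pieces_b <- character(0)
  for (i in seq_len(nrow(dec))) {
    el <- dec[i, ]
    if (!is.null(a_limit) && el$a_start >= a_limit && el$b_start >= b_limit) break
    if (el$type == "run") {
      ae <- el$a_end; be <- el$b_end
      if (!is.null(a_limit) && ae > a_limit) {
        ae <- a_limit; be <- el$b_start + (a_limit - el$a_start)
      }
      s <- substr0(a, el$a_start, ae)
      pieces_a <- c(pieces_a, s)
      pieces_b <- c(pieces_b, s)
    } else {
      va <- substr0(a, el$a_start, el$a_end)
      vb <- substr0(b, el$b_start, el$b_end)
      sub <- align_connector(va, vb, params)
      pieces_a <- c(pieces_a, sub$a_aln)
      pieces_b <- c(pieces_b, sub$b_aln)
    }
  }
  list(a_aln = paste(pieces_a, collapse = ""),
       b_aln = paste(pieces_b, collapse = ""))
}

align_connector <- function(va, vb, params) {
  la <- nchar(va); lb <- nchar(vb)
  if (la == 0L && lb == 0L) return(list(a_aln = "", b_aln = ""))
  if (la == 0L) return(list(a_aln = strrep("-", lb), b_aln = vb))
  if (lb == 0L) return(list(a_aln = va, b_aln = strrep("-", la)))
  if (as.numeric(la) * lb <= params$exact_cells) return(dp_align(va, vb, params))
  # dissimilar block beyond the DP budget: emit as two adjacent gap blocks
  list(a_aln = paste0(va, strrep("-", lb)),
       b_aln = paste0(strrep("-", la), vb))
}
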
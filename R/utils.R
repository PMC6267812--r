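#' @importFrom methods is
#' @importFrom stats setNames
#' @importFrom utils head tail write.table read.delim
NULL

# Internal helpers shared across modules. Sequences travel as plain uppercase
# character scalars; hot loops work on raw vectors from charToRaw().

RAW_GAP <- charToRaw("-")
RAW_N <- charToRaw("N")

seq_as_raw <- function(s) charToRaw(s)

raw_as_seq <- function(r) rawToChar(r)

#' Reverse complement of a DNA string
#'
#' Thin character-in/character-out wrapper around
#' [Biostrings::reverseComplement()].
#'
#' @param s DNA string over A, C, G, T, N.
#' @return The reverse complement as a character scalar.
#' @export
revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Random DNA string with a given GC content
#'
#' Draws bases i.i.d. with P(G) = P(C) = gc/2. Uses the session RNG, so wrap
#' in `set.seed()` for reproducibility.
#'
#' @param n length in bases.
#' @param gc target GC fraction in `[0, 1]`.
#' @return A character scalar of length-`n` DNA.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# substring without the pitfalls: 0-based half-open interval [from, to)
substr0 <- function(s, from, to) {
  if (to <= from) return("")
  substr(s, from + 1L, to)
}

# length of the common prefix of a[ia..] and b[ib..] (raw vectors, 1-based
# start indices), capped at `max_len`; chunked so long extensions stay cheap
common_prefix_len <- function(a, ia, b, ib, max_len) {
  total <- 0L
  block <- 4096L
  while (total < max_len) {
    take <- min(block, max_len - total)
    xa <- a[(ia + total):(ia + total + take - 1L)]
    xb <- b[(ib + total):(ib + total + take - 1L)]
    neq <- which(xa != xb)
    if (length(neq)) return(total + neq[1L] - 1L)
    total <- total + take
  }
  total
}

validate_dna <- function(s, what = "sequence") {
  if (!is.character(s) || length(s) != 1L) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  if (nchar(s) == 0L) stop(what, " is empty", call. = FALSE)
  s <- toupper(s)
  bad <- gsub("[ACGTN]", "", s)
  if (nchar(bad) > 0L) {
    stop(what, " contains characters outside A/C/G/T/N: ",
         paste(unique(strsplit(substr(bad, 1, 10), "")[[1]]), collapse = ""),
         call. = FALSE)
  }
  s
}
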
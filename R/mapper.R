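# mapper: decompose a pair of near-identical genomes into alternating exactly
# identical "runs" and divergent "connectors", then type the differences.
#
# Runs are found by anchoring on k-mers (k = min_run) that occur exactly once
# in each sequence, chaining the anchors colinearly (longest increasing
# subsequence; ties resolved leftmost in genome a), collapsing same-diagonal
# anchors, extending each anchor region to its maximal exact match, and
# trimming overlaps between consecutive runs.

#' Decompose two genomes into identical runs and divergent connectors
#'
#' Splits sequences `a` and `b` into an alternating series of runs
#' (subsequences that are completely identical between the genomes) and
#' connectors (the divergent material between runs, either side of which may
#' be empty). Concatenating the a-side (resp. b-side) pieces in order
#' reconstructs each input exactly.
#'
#' @param a,b [genome_record()]s or plain DNA strings.
#' @param min_run minimum run length in bases; also the anchor k-mer size.
#'   Runs shorter than this are absorbed into connectors.
#' @return A data.frame of class `pairseg_decomposition` with columns
#'   `type` ("run"/"connector"), `a_start`, `a_end`, `b_start`, `b_end`
#'   (0-based half-open) and `length` (run length; NA for connectors), plus
#'   attributes `a_seq`, `b_seq`. If the genomes share no run of at least
#'   `min_run` bases the result is a single whole-genome connector.
#' @export
decompose <- function(a, b, min_run = 20L) {
  sa <- genome_seq(a); sb <- genome_seq(b)
  stopifnot(min_run >= 1L)
  na <- nchar(sa); nb <- nchar(sb)
  if (na == 0L || nb == 0L) stop("sequences must be non-empty", call. = FALSE)

  runs <- find_runs(sa, sb, as.integer(min_run))
  elements <- interleave_runs(runs, na, nb)
  structure(elements, class = c("pairseg_decomposition", "data.frame"),
            a_seq = sa, b_seq = sb, min_run = as.integer(min_run))
}

genome_seq <- function(x) {
  if (inherits(x, "genome_record")) x$sequence else validate_dna(x)
}

# maximal colinear exact-match runs, as a data.frame(a_start, a_end, b_start,
# b_end) in 0-based half-open coordinates
find_runs <- function(sa, sb, k) {
  na <- nchar(sa); nb <- nchar(sb)
  empty <- data.frame(a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer())
  if (na < k || nb < k) return(empty)

  ka <- substring(sa, 1:(na - k + 1L), k:na)
  kb <- substring(sb, 1:(nb - k + 1L), k:nb)
  ua <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  ub <- !(duplicated(kb) | duplicated(kb, fromLast = TRUE))
  pos_a <- which(ua)
  hit <- match(ka[pos_a], kb[which(ub)])
  keep <- !is.na(hit)
  if (!any(keep)) return(add_boundary_runs(empty, sa, sb, k))
  pa <- pos_a[keep]                 # 1-based a positions of anchors
  pb <- which(ub)[hit[keep]]        # matching 1-based b positions
  # colinear chain: strictly increasing pb over anchors sorted by pa
  sel <- chain_lis(pb)
  pa <- pa[sel]; pb <- pb[sel]

  # collapse same-diagonal anchors that overlap or abut
  d <- pb - pa
  brk <- c(TRUE, d[-1L] != d[-length(d)] | diff(pa) > k)
  grp <- cumsum(brk)
  a_start <- tapply(pa, grp, min) - 1L          # to 0-based
  a_end <- tapply(pa, grp, max) + k - 1L        # half-open
  b_start <- tapply(pb, grp, min) - 1L
  runs <- data.frame(a_start = as.integer(a_start), a_end = as.integer(a_end),
                     b_start = as.integer(b_start))
  runs$b_end <- runs$b_start + (runs$a_end - runs$a_start)

  runs <- extend_runs(runs, sa, sb)
  runs <- resolve_run_overlaps(runs, k)
  add_boundary_runs(runs, sa, sb, k)
}

# anchor k-mers must be unique in both sequences, so an exact match at the
# very start or end of the pair can be missed when its k-mers recur
# elsewhere; recover those from direct prefix/suffix comparison
add_boundary_runs <- function(runs, sa, sb, k) {
  ra <- seq_as_raw(sa); rb <- seq_as_raw(sb)
  na <- length(ra); nb <- length(rb)
  cap_pre <- if (nrow(runs)) min(runs$a_start[1L], runs$b_start[1L]) else min(na, nb)
  if (cap_pre >= k) {
    p <- common_prefix_len(ra, 1L, rb, 1L, cap_pre)
    if (p >= k) {
      runs <- rbind(data.frame(a_start = 0L, a_end = p, b_start = 0L, b_end = p),
                    runs)
    }
  }
  n <- nrow(runs)
  cap_suf <- if (n) min(na - runs$a_end[n], nb - runs$b_end[n]) else min(na, nb)
  if (cap_suf >= k) {
    s <- 0L
    while (s < cap_suf && ra[na - s] == rb[nb - s]) s <- s + 1L
    if (s >= k) {
      runs <- rbind(runs, data.frame(a_start = na - s, a_end = na,
                                     b_start = nb - s, b_end = nb))
    }
  }
  rownames(runs) <- NULL
  runs
}

# longest strictly increasing subsequence of v (returns indices), O(n log n)
# patience algorithm; replacing equal tails keeps chains leftmost in genome a
chain_lis <- function(v) {
  n <- length(v)
  if (n <= 1L || !is.unsorted(v, strictly = TRUE)) return(seq_len(n))
  tails <- numeric(n)       # smallest tail value of an increasing chain of each length
  tails_idx <- integer(n)
  parent <- integer(n)
  L <- 0L
  for (i in seq_len(n)) {
    vi <- v[i]
    lo <- 1L; hi <- L + 1L  # binary search: first tail >= vi
    while (lo < hi) {
      mid <- (lo + hi) %/% 2L
      if (tails[mid] < vi) lo <- mid + 1L else hi <- mid
    }
    j <- lo
    parent[i] <- if (j > 1L) tails_idx[j - 1L] else 0L
    tails[j] <- vi
    tails_idx[j] <- i
    if (j > L) L <- j
  }
  sel <- integer(L)
  at <- tails_idx[L]
  for (p in L:1L) { sel[p] <- at; at <- parent[at] }
  sel
}

extend_runs <- function(runs, sa, sb) {
  if (nrow(runs) == 0L) return(runs)
  ra <- seq_as_raw(sa); rb <- seq_as_raw(sb)
  na <- length(ra); nb <- length(rb)
  for (i in seq_len(nrow(runs))) {
    # right extension
    max_r <- min(na - runs$a_end[i], nb - runs$b_end[i])
    if (max_r > 0L) {
      ext <- common_prefix_len(ra, runs$a_end[i] + 1L, rb, runs$b_end[i] + 1L, max_r)
      runs$a_end[i] <- runs$a_end[i] + ext
      runs$b_end[i] <- runs$b_end[i] + ext
    }
    # left extension (compare reversed prefixes)
    max_l <- min(runs$a_start[i], runs$b_start[i])
    if (max_l > 0L) {
      ext <- 0L
      while (ext < max_l &&
             ra[runs$a_start[i] - ext] == rb[runs$b_start[i] - ext]) {
        ext <- ext + 1L
      }
      runs$a_start[i] <- runs$a_start[i] - ext
      runs$b_start[i] <- runs$b_start[i] - ext
    }
  }
  runs
}

resolve_run_overlaps <- function(runs, min_run) {
  repeat {
    n <- nrow(runs)
    if (n <= 1L) break
    changed <- FALSE
    keep <- rep(TRUE, n)
    last <- 1L
    for (j in 2L:n) {
      same_diag <- (runs$b_start[j] - runs$a_start[j]) ==
        (runs$b_start[last] - runs$a_start[last])
      if (same_diag && runs$a_start[j] <= runs$a_end[last]) {
        # contiguous identical region: merge into the previous run
        runs$a_end[last] <- max(runs$a_end[last], runs$a_end[j])
        runs$b_end[last] <- max(runs$b_end[last], runs$b_end[j])
        keep[j] <- FALSE
        changed <- TRUE
        next
      }
      ov <- max(runs$a_end[last] - runs$a_start[j],
                runs$b_end[last] - runs$b_start[j], 0L)
      if (ov > 0L) {
        runs$a_start[j] <- runs$a_start[j] + ov
        runs$b_start[j] <- runs$b_start[j] + ov
        changed <- TRUE
      }
      if (runs$a_end[j] - runs$a_start[j] < min_run) {
        keep[j] <- FALSE
        changed <- TRUE
      } else {
        last <- j
      }
    }
    runs <- runs[keep, , drop = FALSE]
    rownames(runs) <- NULL
    if (!changed) break
  }
  runs[runs$a_end - runs$a_start >= min_run, , drop = FALSE]
}

interleave_runs <- function(runs, na, nb) {
  rows <- list()
  add <- function(type, as_, ae, bs, be) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, a_start = as_, a_end = ae, b_start = bs, b_end = be,
      length = if (type == "run") ae - as_ else NA_integer_)
  }
  ca <- 0L; cb <- 0L
  if (nrow(runs)) {
    for (i in seq_len(nrow(runs))) {
      if (runs$a_start[i] > ca || runs$b_start[i] > cb) {
        add("connector", ca, runs$a_start[i], cb, runs$b_start[i])
      }
      add("run", runs$a_start[i], runs$a_end[i], runs$b_start[i], runs$b_end[i])
      ca <- runs$a_end[i]; cb <- runs$b_end[i]
    }
  }
  if (ca < na || cb < nb) add("connector", ca, na, cb, nb)
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(type = character(), a_start = integer(), a_end = integer(),
                      b_start = integer(), b_end = integer(), length = integer())
  }
  rownames(out) <- NULL
  out
}

#' Check that a decomposition reconstructs its inputs
#'
#' @param dec a `pairseg_decomposition`.
#' @return TRUE invisibly; errors if either genome is not rebuilt byte-exactly.
#' @export
check_reconstruction <- function(dec) {
  sa <- attr(dec, "a_seq"); sb <- attr(dec, "b_seq")
  pieces_a <- mapply(substr0, dec$a_start, dec$a_end, MoreArgs = list(s = sa))
  pieces_b <- mapply(substr0, dec$b_start, dec$b_end, MoreArgs = list(s = sb))
  ra <- paste(pieces_a[order(dec$a_start)], collapse = "")
  rb <- paste(pieces_b[order(dec$b_start)], collapse = "")
  if (!identical(ra, sa) || !identical(rb, sb)) {
    stop("decomposition does not reconstruct its inputs", call. = FALSE)
  }
  runs <- dec[dec$type == "run", , drop = FALSE]
  if (nrow(runs)) {
    same <- mapply(function(as_, ae, bs, be) {
      identical(substr0(sa, as_, ae), substr0(sb, bs, be))
    }, runs$a_start, runs$a_end, runs$b_start, runs$b_end)
    if (!all(same)) stop("run subsequences are not identical", call. = FALSE)
  }
  invisible(TRUE)
}

#' Type the differences of a run/connector decomposition
#'
#' Produces one difference record per event: equal-length 1-to-1 substitution
#' is a `point_mutation`; a 0-to-1 or 1-to-0 connector is a `one_base_indel`;
#' sides that are reverse complements of each other are an `inversion`; a
#' connector whose extra material is a whole number of tandem copies of a
#' 7-16 bp unit present on both sides of the locus is a
#' `copy_number_variation`; a connector with one side empty and the other
#' longer than `long_indel_min` is a `long_indel`; everything else with both
#' sides at most `long_indel_min` is a `few_base_difference`, and larger
#' two-sided connectors are reported as `long_indel` with a replacement note.
#'
#' @param dec a `pairseg_decomposition` from [decompose()].
#' @param long_indel_min boundary between few-base differences and long
#'   indels, in bases.
#' @param unit_range tandem-repeat unit lengths to consider.
#' @return A data.frame of class `pairseg_diffs` with columns `category`,
#'   `a_start`, `a_end`, `b_start`, `b_end`, `detail`.
#' @export
type_differences <- function(dec, long_indel_min = 50L, unit_range = c(7L, 16L)) {
  stopifnot(inherits(dec, "pairseg_decomposition"))
  sa <- attr(dec, "a_seq"); sb <- attr(dec, "b_seq")
  conns <- dec[dec$type == "connector", , drop = FALSE]
  recs <- lapply(seq_len(nrow(conns)), function(i) {
    type_one_connector(conns[i, ], sa, sb, long_indel_min, unit_range)
  })
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(category = character(), a_start = integer(), a_end = integer(),
               b_start = integer(), b_end = integer(), detail = character())
  rownames(out) <- NULL
  class(out) <- c("pairseg_diffs", "data.frame")
  out
}

type_one_connector <- function(cn, sa, sb, long_indel_min, unit_range) {
  va <- substr0(sa, cn$a_start, cn$a_end)
  vb <- substr0(sb, cn$b_start, cn$b_end)
  la <- nchar(va); lb <- nchar(vb)
  rec <- function(category, detail) {
    data.frame(category = category, a_start = cn$a_start, a_end = cn$a_end,
               b_start = cn$b_start, b_end = cn$b_end, detail = detail)
  }
  if (la == 1L && lb == 1L) return(rec("point_mutation", paste0(va, ">", vb)))
  if ((la == 0L && lb == 1L) || (la == 1L && lb == 0L)) {
    return(rec("one_base_indel",
               if (la == 0L) paste0("+", vb, " in b") else paste0("+", va, " in a")))
  }
  if (la > 0L && lb > 0L && la == lb && identical(va, revcomp(vb))) {
    return(rec("inversion", sprintf("%d bp inverted", la)))
  }
  cnv <- connector_cnv(cn, sa, sb, unit_range)
  if (!is.null(cnv)) return(rec("copy_number_variation", cnv))
  if ((la == 0L || lb == 0L) && max(la, lb) > long_indel_min) {
    carrier <- if (la > lb) "a" else "b"
    return(rec("long_indel", sprintf("%d bp insertion in %s", max(la, lb), carrier)))
  }
  if (la <= long_indel_min && lb <= long_indel_min) {
    return(rec("few_base_difference", sprintf("%d vs %d bp", la, lb)))
  }
  rec("long_indel", sprintf("replacement-like, %d vs %d bp", la, lb))
}

# tandem-CNV check for a connector: the extra material must be a whole number
# of copies of a 7-16 bp unit that is also present in the flanking sequence of
# both genomes. Returns a detail string, or NULL.
connector_cnv <- function(cn, sa, sb, unit_range) {
  va <- substr0(sa, cn$a_start, cn$a_end)
  vb <- substr0(sb, cn$b_start, cn$b_end)
  extra <- if (nchar(va) >= nchar(vb)) va else vb
  if (nchar(extra) < 2L * unit_range[1L]) return(NULL)
  hit <- detect_tandem_unit(extra, min_unit = unit_range[1L], max_unit = unit_range[2L])
  if (is.null(hit)) return(NULL)
  if (nchar(extra) %% hit$unit_length != 0L) return(NULL)
  ca <- tandem_copies_at(sa, cn$a_start, cn$a_end, hit$unit)
  cb <- tandem_copies_at(sb, cn$b_start, cn$b_end, hit$unit)
  if (ca == 0L && cb == 0L) return(NULL)
  if (min(ca, cb) < 1L || max(ca, cb) < 2L) return(NULL)
  sprintf("unit %s: %d copies in a, %d in b", hit$unit, ca, cb)
}

# number of tandem copies of `unit` in genome `s` covering interval
# [start, end), extended into both flanks
tandem_copies_at <- function(s, start, end, unit) {
  u <- nchar(unit)
  n <- nchar(s)
  lo <- start; hi <- end
  while (lo - u >= 0L && substr0(s, lo - u, lo) == unit) lo <- lo - u
  while (hi + u <= n && substr0(s, hi, hi + u) == unit) hi <- hi + u
  # align the phase: count whole copies tiling [lo, hi)
  span <- hi - lo
  copies <- 0L
  at <- lo
  while (at + u <= hi && substr0(s, at, at + u) == unit) {
    copies <- copies + 1L
    at <- at + u
  }
  copies
}
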
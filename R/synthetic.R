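# synthetic_data: generate pairs of closely related circular bacterial
# chromosomes with a known set of differences — point mutations, 1-base
# indels (intergenic and CDS-disrupting frameshifts), mobile-element
# insertions with TA target-site duplications, long inversions bounded by
# planted inverted repeats, tandem-repeat copy-number variations, and
# prophage-like strain-specific blocks — together with an exhaustive
# ground-truth table. The generator is the oracle for every other module.

#' Synthetic MITE-like element
#'
#' A fixed 123-bp synthetic construct used as the default mobile element of
#' the generator: 25-bp terminal inverted repeats around a unique core. It
#' inserts at TA sites with a TA target-site duplication.
#'
#' @format A character scalar of 123 bases.
#' @export
SYNTHETIC_MITE <- paste0(
  "GGCCTTACGAATCGTTAGCCAGTCA",                                  # left TIR
  "ACGGATTCACCGGTTAAGCGTGCAGATTCCGGAATCTTGACGCATGGCTTAAGCCGTACGGATCCAGTTGACA",
  "TGACTGGCTAACGATTCGTAAGGCC")                                  # right TIR

#' Specification of a synthetic genome pair
#'
#' Defaults emulate a pair of ~99.7%-identical bacterial chromosomes at desk
#' scale: event densities follow the per-megabase rates observed between
#' closely related strain pairs (thousands of point mutations, tens of
#' frameshifts and strain-specific regions per genome), scaled to
#' `genome_length`. Events are placed at least `spacing` bases apart so that
#' every seeded event is recovered as its own connector/divSEG.
#'
#' @param genome_length ancestor length in bases.
#' @param gc_content ancestor GC fraction.
#' @param n_snp,n_1bp_indel,n_frameshift,n_inversion,n_tandem_cnv,n_mge_insertion,n_block_indel
#'   event counts. `n_1bp_indel` events are intergenic; `n_frameshift` are
#'   1-base indels placed inside planted CDSs (emitted as split ORFs with no
#'   pseudo flag).
#' @param block_length_range,inversion_length_range event size ranges (bp).
#' @param mge_library character vector of element sequences (inserted with a
#'   TA target-site duplication).
#' @param tandem_unit_range tandem-repeat unit lengths (bp).
#' @param tandem_copies_range ancestral copy numbers.
#' @param tandem_delta_range extra copies gained by the carrier.
#' @param ir_length length of the inverted repeats planted at inversion
#'   boundaries.
#' @param spacing minimum distance between event footprints (bp).
#' @param gene_grid plant a CDS grid (one ~900 bp gene per ~1.5 kb)?
#' @param gene_length,gene_spacing grid geometry (bp; `gene_length` must be a
#'   multiple of 3).
#' @param n_rrna number of planted identical rRNA operons.
#' @param seed integer seed recorded in every fixture.
#' @return list of class `mutation_spec`.
#' @export
mutation_spec <- function(genome_length = 200000L, gc_content = 0.43,
                          n_snp = 200L, n_1bp_indel = 12L, n_frameshift = 4L,
                          n_inversion = 1L, n_tandem_cnv = 2L,
                          n_mge_insertion = 4L, n_block_indel = 3L,
                          block_length_range = c(1000L, 8000L),
                          inversion_length_range = c(2000L, 5000L),
                          mge_library = SYNTHETIC_MITE,
                          tandem_unit_range = c(7L, 12L),
                          tandem_copies_range = c(10L, 15L),
                          tandem_delta_range = c(15L, 25L),
                          ir_length = 40L, spacing = 200L,
                          gene_grid = TRUE, gene_length = 900L,
                          gene_spacing = 1500L, n_rrna = 0L,
                          n_unique_genes = 5L, n_dup_genes = 2L, seed = 1L) {
  stopifnot(genome_length > 0, gene_length %% 3L == 0L,
            all(c(n_snp, n_1bp_indel, n_frameshift, n_inversion, n_tandem_cnv,
                  n_mge_insertion, n_block_indel) >= 0L))
  if (n_frameshift > 0L && !gene_grid) {
    stop("n_frameshift > 0 requires gene_grid = TRUE", call. = FALSE)
  }
  structure(as.list(environment()), class = "mutation_spec")
}

SENSE_CODONS <- {
  nt <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(nt, nt, paste0), nt, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

# random CDS in forward (reading) orientation: sampled start codon, sense
# internal codons with a planted in-frame ATG at 60%, sampled stop codon
random_cds <- function(gene_length) {
  n_codon <- gene_length %/% 3L
  met_at <- max(2L, floor(n_codon * 0.6))
  start_codon <- sample(c("ATG", "GTG", "TTG"), 1L, prob = c(0.80, 0.14, 0.06))
  internal <- sample(SENSE_CODONS, n_codon - 2L, replace = TRUE)
  internal[met_at - 1L] <- "ATG"
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
  paste0(start_codon, paste(internal, collapse = ""), stop_codon)
}

# near-duplicate of a CDS: ~10% of internal codons replaced by random sense
# codons (protein identity stays well above the 75% homolog threshold)
mutate_cds_copy <- function(nt, frac = 0.10) {
  n_codon <- nchar(nt) %/% 3L
  codons <- substring(nt, 3L * (seq_len(n_codon) - 1L) + 1L, 3L * seq_len(n_codon))
  pick <- which(stats::runif(n_codon - 2L) < frac) + 1L
  codons[pick] <- sample(SENSE_CODONS, length(pick), replace = TRUE)
  paste(codons, collapse = "")
}

#' Generate the ancestral genome of a synthetic pair
#'
#' Random sequence of the requested length and GC content; when
#' `gene_grid` is set, a CDS is planted every `gene_spacing` bases with
#' start codons drawn as ATG/GTG/TTG in 0.80/0.14/0.06 proportions, no
#' internal stop (bacterial code), and an internal in-frame ATG at 60% of
#' the gene (used by frameshift events to guarantee a translatable split).
#' Reproducible from `spec$seed`.
#'
#' @param spec a [mutation_spec()].
#' @return An annotated [genome_record()].
#' @export
generate_ancestor <- function(spec) {
  stopifnot(inherits(spec, "mutation_spec"))
  set.seed(spec$seed)
  s <- random_dna(spec$genome_length, spec$gc_content)
  feats <- feature_table()
  if (spec$gene_grid && spec$genome_length >= spec$gene_spacing + 1000L) {
    starts <- seq(500L, spec$genome_length - spec$gene_spacing,
                  by = spec$gene_spacing)
    rows <- list()
    rrna_seq <- if (spec$n_rrna > 0L) random_dna(1400L, spec$gc_content) else NULL
    for (g in seq_along(starts)) {
      st <- starts[g]
      if (spec$n_rrna > 0L && g <= spec$n_rrna) {
        s <- paste0(substr0(s, 0L, st), rrna_seq,
                    substr0(s, st + 1400L, spec$genome_length))
        rows[[g]] <- feature_table(
          locus_tag = sprintf("SYN_%04d", g), kind = "rRNA",
          start = st, end = st + 1400L, strand = "+",
          pseudo = FALSE, product_name = "16S ribosomal RNA")
        next
      }
      cds <- random_cds(spec$gene_length)
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") cds else revcomp(cds)
      s <- paste0(substr0(s, 0L, st), ins,
                  substr0(s, st + nchar(ins), spec$genome_length))
      rows[[g]] <- feature_table(
        locus_tag = sprintf("SYN_%04d", g), kind = "CDS",
        start = st, end = st + nchar(ins), strand = strand,
        pseudo = FALSE, product_name = "hypothetical protein")
    }
    feats <- do.call(rbind, rows)
  }
  genome_record("SYN_ANC", s, circular = TRUE, features = feats)
}

# intergenic mask (logical over 0-based positions) with a safety pad
intergenic_mask <- function(genome, pad = 20L) {
  ok <- rep(TRUE, genome$length)
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    lo <- max(1L, f$start[i] + 1L - pad)
    hi <- min(genome$length, f$end[i] + pad)
    ok[lo:hi] <- FALSE
  }
  ok[seq_len(min(500L, genome$length))] <- FALSE
  ok[max(1L, genome$length - 500L):genome$length] <- FALSE
  ok
}

#' Derive two descendant genomes and a ground-truth table from an ancestor
#'
#' Plants structural prerequisites into the ancestor (inverted repeats at
#' inversion boundaries, ancestral tandem arrays, TA sites at element
#' insertion points), then applies each event to exactly one descendant
#' (chosen by a seeded coin). Frameshift events split a planted CDS into two
#' ORFs in the carrier's emitted annotation without setting a pseudo flag.
#' Event footprints are at least `spec$spacing` bases apart.
#'
#' @param ancestor result of [generate_ancestor()] (same spec).
#' @param spec the [mutation_spec()].
#' @return list of class `synthetic_pair`: `a`, `b` (annotated
#'   [genome_record()]s), `truth` (the mutation truth table), `ancestor`
#'   (the prepared ancestor), `spec`.
#' @export
mutate_pair <- function(ancestor, spec) {
  stopifnot(inherits(spec, "mutation_spec"), inherits(ancestor, "genome_record"))
  set.seed(spec$seed + 1L)
  n_events <- spec$n_snp + spec$n_1bp_indel + spec$n_frameshift +
    spec$n_inversion + spec$n_tandem_cnv + spec$n_mge_insertion +
    spec$n_block_indel
  if (n_events * spec$spacing > 0.8 * spec$genome_length) {
    stop("infeasible packing: ", n_events, " events with spacing ",
         spec$spacing, " exceed genome length ", spec$genome_length,
         call. = FALSE)
  }

  prep <- ancestor$sequence
  feats <- ancestor$features
  inter <- intergenic_mask(ancestor)
  occupied <- matrix(numeric(0), ncol = 2)   # [start, end) footprints + spacing

  free_at <- function(s, e) {
    s2 <- s - spec$spacing; e2 <- e + spec$spacing
    nrow(occupied) == 0 || !any(occupied[, 1] < e2 & occupied[, 2] > s2)
  }
  claim <- function(s, e) occupied <<- rbind(occupied, c(s, e))

  draw_point <- function(need_intergenic, footprint, tries = 20000L) {
    for (t in seq_len(tries)) {
      p <- sample.int(spec$genome_length - footprint - 600L, 1L) + 500L
      if (need_intergenic && !all(inter[(p + 1L):(p + max(footprint, 1L))])) next
      if (!free_at(p, p + footprint)) next
      return(p)
    }
    stop("infeasible packing: could not place an event (spacing ",
         spec$spacing, ")", call. = FALSE)
  }

  events <- list()
  add_event <- function(type, s, e, carrier, payload = "", unit = NA_character_,
                        anc_copies = NA_integer_, carrier_copies = NA_integer_,
                        locus = NA_character_) {
    events[[length(events) + 1L]] <<- list(
      event_id = length(events) + 1L, type = type, anc_start = s, anc_end = e,
      carrier = carrier, payload = payload, unit = unit,
      anc_copies = anc_copies, carrier_copies = carrier_copies, locus = locus)
    claim(s, e)
  }
  coin <- function() sample(c("a", "b"), 1L)

  ## --- structural planting + event registration (prepared-ancestor coords) ---
  # inversions: intergenic boundary zones, interior may span genes
  for (k in seq_len(spec$n_inversion)) {
    placed <- FALSE
    for (t in seq_len(20000L)) {
      len <- sample(spec$inversion_length_range[1L]:spec$inversion_length_range[2L], 1L)
      s <- sample.int(spec$genome_length - len - 1200L, 1L) + 500L
      e <- s + len
      irz1 <- (s + 1L):(s + spec$ir_length)
      irz2 <- (e - spec$ir_length + 1L):e
      if (!all(inter[irz1]) || !all(inter[irz2])) next
      cut <- feats$start < e & feats$end > s &
        (feats$start < s + spec$ir_length | feats$end > e - spec$ir_length)
      if (any(cut)) next                       # no feature across a boundary
      if (!free_at(s, e)) next
      ir <- random_dna(spec$ir_length, spec$gc_content)
      prep <- paste0(substr0(prep, 0L, s), ir,
                     substr0(prep, s + spec$ir_length, e - spec$ir_length),
                     revcomp(ir), substr0(prep, e, spec$genome_length))
      add_event("inversion", s, e, coin())
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible packing: inversion", call. = FALSE)
  }
  # tandem arrays
  for (k in seq_len(spec$n_tandem_cnv)) {
    u <- sample(spec$tandem_unit_range[1L]:spec$tandem_unit_range[2L], 1L)
    anc_copies <- sample(spec$tandem_copies_range[1L]:spec$tandem_copies_range[2L], 1L)
    delta <- sample(spec$tandem_delta_range[1L]:spec$tandem_delta_range[2L], 1L)
    repeat {
      unit <- random_dna(u, spec$gc_content)
      # avoid a unit that is itself periodic or starts/ends alike (phase ambiguity)
      if (is.null(detect_tandem_unit(strrep(unit, 4L), 2L, u - 1L,
                                     max_mismatch_frac = 0, min_coverage = 1)) &&
          substr(unit, 1L, 1L) != substr(unit, u, u)) break
    }
    arr_len <- u * anc_copies
    s <- draw_point(TRUE, arr_len)
    prep <- paste0(substr0(prep, 0L, s), strrep(unit, anc_copies),
                   substr0(prep, s + arr_len, spec$genome_length))
    add_event("tandem_cnv", s, s + arr_len, coin(), payload = strrep(unit, delta),
              unit = unit, anc_copies = anc_copies,
              carrier_copies = anc_copies + delta)
  }
  # mobile-element insertions at TA sites
  for (k in seq_len(spec$n_mge_insertion)) {
    p <- draw_point(TRUE, 2L)
    prep <- paste0(substr0(prep, 0L, p), "TA",
                   substr0(prep, p + 2L, spec$genome_length))
    el <- spec$mge_library[[((k - 1L) %% length(spec$mge_library)) + 1L]]
    add_event("mge_insertion", p, p + 2L, coin(), payload = paste0(el, "TA"))
  }
  # prophage-like strain-specific blocks, carrying the seeded strain-specific
  # genes: `n_unique_genes` novel CDSs plus `n_dup_genes` near-duplicates of
  # grid genes (close homologs in the other strain)
  gene_queue <- list()
  if (spec$gene_grid && spec$n_block_indel > 0L) {
    grid_cds <- which(feats$kind == "CDS")
    for (k in seq_len(spec$n_unique_genes)) {
      gene_queue[[length(gene_queue) + 1L]] <- list(
        role = "unique", nt = random_cds(spec$gene_length), source = NA_character_)
    }
    for (k in seq_len(spec$n_dup_genes)) {
      src <- feats[grid_cds[sample.int(length(grid_cds), 1L)], ]
      src_nt <- substr0(prep, src$start, src$end)
      if (src$strand == "-") src_nt <- revcomp(src_nt)
      gene_queue[[length(gene_queue) + 1L]] <- list(
        role = "dup", nt = mutate_cds_copy(src_nt), source = src$locus_tag)
    }
  }
  block_lens <- if (spec$n_block_indel > 0L)
    sample(spec$block_length_range[1L]:spec$block_length_range[2L],
           spec$n_block_indel, replace = TRUE) else integer()
  # ensure total capacity for the seeded genes (grow the last block if needed)
  step <- spec$gene_length + 600L
  block_capacity <- function(L) max(0L, (L - spec$gene_length - 600L) %/% step + 1L)
  if (length(block_lens)) {
    while (sum(vapply(block_lens, block_capacity, 0L)) < length(gene_queue)) {
      block_lens[length(block_lens)] <- block_lens[length(block_lens)] + step
    }
  }
  gq_at <- 1L
  planted <- list()
  for (k in seq_len(spec$n_block_indel)) {
    len <- block_lens[k]
    payload <- random_dna(len, spec$gc_content)
    block_feats <- NULL
    off <- 300L
    rows_bf <- list()
    while (gq_at <= length(gene_queue) &&
           off + spec$gene_length + 300L <= len) {
      gq <- gene_queue[[gq_at]]
      strand <- sample(c("+", "-"), 1L)
      ins <- if (strand == "+") gq$nt else revcomp(gq$nt)
      payload <- paste0(substr0(payload, 0L, off), ins,
                        substr0(payload, off + nchar(ins), len))
      tag <- sprintf("SYNB_%02d_%02d", k, length(rows_bf) + 1L)
      rows_bf[[length(rows_bf) + 1L]] <- cbind(
        feature_table(locus_tag = tag, kind = "CDS", start = off,
                      end = off + nchar(ins), strand = strand, pseudo = FALSE,
                      product_name = "hypothetical protein"),
        data.frame(role = gq$role, source = gq$source))
      gq_at <- gq_at + 1L
      off <- off + spec$gene_length + 600L
    }
    if (length(rows_bf)) block_feats <- do.call(rbind, rows_bf)
    p <- draw_point(TRUE, 0L)
    # pin the payload edges: identical edge bases would let the flanking
    # exact-match runs slide into the insert and blur the breakpoint
    first_ok <- setdiff(c("A", "C", "G", "T"), substr0(prep, p, p + 1L))
    last_ok <- setdiff(c("A", "C", "G", "T"), substr0(prep, p - 1L, p))
    substr(payload, 1L, 1L) <- sample(first_ok, 1L)
    substr(payload, len, len) <- sample(last_ok, 1L)
    add_event("block_indel", p, p, coin(), payload = payload)
    if (!is.null(block_feats)) {
      events[[length(events)]]$features <- block_feats
      planted[[length(planted) + 1L]] <- cbind(
        block_feats[, c("locus_tag", "role", "source")],
        data.frame(carrier = events[[length(events)]]$carrier))
    }
  }
  if (gq_at <= length(gene_queue)) {
    stop("infeasible packing: strain-specific genes exceed block capacity",
         call. = FALSE)
  }
  # intergenic 1-base indels; neighbours must differ from the indel base so
  # the event position is unambiguous (no homopolymer shift) and the truth
  # table coordinates are exact
  for (k in seq_len(spec$n_1bp_indel)) {
    if (sample(c(TRUE, FALSE), 1L)) {
      repeat {
        p <- draw_point(TRUE, 1L)
        nb <- c(substr0(prep, p - 1L, p), substr0(prep, p, p + 1L))
        base <- sample(setdiff(c("A", "C", "G", "T"), nb), 1L)
        break
      }
      add_event("one_base_insertion", p, p, coin(), payload = base)
    } else {
      repeat {
        p <- draw_point(TRUE, 1L)
        here <- substr0(prep, p, p + 1L)
        if (here != substr0(prep, p - 1L, p) &&
            here != substr0(prep, p + 1L, p + 2L)) break
      }
      add_event("one_base_deletion", p, p + 1L, coin())
    }
  }
  # CDS frameshifts (validated for a clean two-ORF split)
  # frameshift targets must not be the source of a near-duplicate gene
  # (the homolog filter's ground truth assumes the source stays intact)
  dup_sources <- unlist(lapply(gene_queue, function(q) q$source))
  dup_sources <- dup_sources[!is.na(dup_sources)]
  cds_rows <- which(feats$kind == "CDS" & !feats$locus_tag %in% dup_sources)
  fs_used <- integer(0)
  resample1 <- function(x) x[sample.int(length(x), 1L)]
  for (k in seq_len(spec$n_frameshift)) {
    placed <- FALSE
    for (t in seq_len(5000L)) {
      gi <- resample1(setdiff(cds_rows, fs_used))
      f <- feats[gi, ]
      glen <- f$end - f$start
      off <- 3L * resample1((glen %/% 9L):(glen %/% 6L))  # middle-ish codon
      insert <- sample(c(TRUE, FALSE), 1L)
      base <- sample(c("A", "C", "G", "T"), 1L)
      sim <- simulate_frameshift(prep, f, off, insert, base)
      if (is.null(sim)) next
      gpos <- if (f$strand == "+") f$start + off else f$end - off
      if (!free_at(f$start, f$end)) next
      # payload is in genome (forward-strand) orientation
      gbase <- if (f$strand == "+") base else revcomp(base)
      add_event(if (insert) "frameshift_insertion" else "frameshift_deletion",
                if (insert) gpos else gpos - (f$strand == "-"),
                if (insert) gpos else gpos + 1L - (f$strand == "-"),
                coin(), payload = if (insert) gbase else "", locus = f$locus_tag)
      events[[length(events)]]$split <- sim
      fs_used <- c(fs_used, gi)
      placed <- TRUE
      break
    }
    if (!placed) stop("infeasible packing: frameshift event", call. = FALSE)
  }
  # point mutations
  for (k in seq_len(spec$n_snp)) {
    p <- draw_point(FALSE, 1L)
    ref <- substr0(prep, p, p + 1L)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    add_event("snp", p, p + 1L, coin(), payload = alt)
  }

  ## --- apply events per descendant -----------------------------------------
  ev <- events[order(vapply(events, `[[`, 0, "anc_start"))]
  pair <- lapply(c(a = "a", b = "b"), function(g) {
    apply_events(prep, feats, ev, g, spec)
  })
  truth <- build_truth(ev, pair$a$shift, pair$b$shift)
  planted_genes <- if (length(planted)) do.call(rbind, planted) else
    data.frame(locus_tag = character(), role = character(),
               source = character(), carrier = character())
  rownames(planted_genes) <- NULL
  structure(list(
    a = genome_record("SYN_A", pair$a$sequence, circular = TRUE,
                      features = pair$a$features),
    b = genome_record("SYN_B", pair$b$sequence, circular = TRUE,
                      features = pair$b$features),
    truth = truth, planted_genes = planted_genes,
    ancestor = genome_record(ancestor$id, prep, circular = TRUE, features = feats),
    spec = spec), class = "synthetic_pair")
}

# can this frameshift be emitted as a clean two-ORF split? Returns reading-
# orientation offsets list(part1_len, part2_off, new_len) or NULL
simulate_frameshift <- function(prep, f, off, insert, base) {
  g <- substr0(prep, f$start, f$end)
  if (f$strand == "-") g <- revcomp(g)
  g2 <- if (insert) paste0(substr(g, 1L, off), base, substr(g, off + 1L, nchar(g)))
  else paste0(substr(g, 1L, off), substr(g, off + 2L, nchar(g)))
  n <- nchar(g2)
  codons <- substring(g2, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
  stops <- which(codons %in% c("TAA", "TAG", "TGA"))
  if (length(stops) == 0L) return(NULL)
  part1_codons <- stops[1L]
  part1_len <- 3L * part1_codons
  if (part1_len <= off) return(NULL)         # stop must come after the indel
  # part 2: first ATG/GTG/TTG in the end-anchored frame after part 1, with no
  # stop before the terminal one
  tail_off <- seq(part1_len, n - 3L)
  tail_off <- tail_off[(n - tail_off) %% 3L == 0L]
  for (q in tail_off) {
    cod <- substr(g2, q + 1L, q + 3L)
    if (!cod %in% c("ATG", "GTG", "TTG")) next
    tcod <- substring(g2, seq(q + 1L, n - 2L, by = 3L), seq(q + 3L, n, by = 3L))
    if (any(tcod[-length(tcod)] %in% c("TAA", "TAG", "TGA"))) return(NULL)
    if (!tcod[length(tcod)] %in% c("TAA", "TAG", "TGA")) return(NULL)
    if (n - q < 90L) return(NULL)            # second ORF at least 30 codons
    return(list(part1_len = part1_len, part2_off = q, new_len = n))
  }
  NULL
}

# build one descendant: sequence, lifted features, and the per-event shift map
apply_events <- function(prep, feats, ev, g, spec) {
  n <- nchar(prep)
  carried <- Filter(function(e) e$carrier == g, ev)
  # edit list in prepared coordinates
  edits <- lapply(carried, function(e) {
    switch(e$type,
      snp = list(s = e$anc_start, e = e$anc_end, payload = e$payload, ev = e),
      one_base_insertion = list(s = e$anc_start, e = e$anc_start, payload = e$payload, ev = e),
      one_base_deletion = list(s = e$anc_start, e = e$anc_end, payload = "", ev = e),
      frameshift_insertion = list(s = e$anc_start, e = e$anc_start, payload = e$payload, ev = e),
      frameshift_deletion = list(s = e$anc_start, e = e$anc_end, payload = "", ev = e),
      mge_insertion = list(s = e$anc_end, e = e$anc_end, payload = e$payload, ev = e),
      block_indel = list(s = e$anc_start, e = e$anc_start, payload = e$payload, ev = e),
      inversion = list(s = e$anc_start, e = e$anc_end,
                       payload = revcomp(substr0(prep, e$anc_start, e$anc_end)), ev = e),
      tandem_cnv = list(s = e$anc_end, e = e$anc_end, payload = e$payload, ev = e))
  })
  # splice
  pieces <- character(0)
  cursor <- 0L
  for (ed in edits) {
    pieces <- c(pieces, substr0(prep, cursor, ed$s), ed$payload)
    cursor <- ed$e
  }
  pieces <- c(pieces, substr0(prep, cursor, n))
  sequence <- paste(pieces, collapse = "")

  # shift of a prepared coordinate x: derived = x + sum of deltas of edits
  # entirely before x (a point insertion exactly at x does not count)
  edit_s <- vapply(edits, `[[`, 0, "s")
  edit_e <- vapply(edits, `[[`, 0, "e")
  edit_d <- vapply(edits, function(ed) nchar(ed$payload) - (ed$e - ed$s), 0)
  shift <- function(x) {
    if (length(edit_s) == 0L) return(as.integer(x))
    before <- function(xi) edit_e < xi | (edit_e == xi & edit_s < edit_e)
    as.integer(vapply(x, function(xi) xi + sum(edit_d[before(xi)]), 0))
  }

  # feature lifting
  inv <- Filter(function(e) e$type == "inversion" && e$carrier == g, ev)
  fs <- Filter(function(e) startsWith(e$type, "frameshift") && e$carrier == g, ev)
  fs_tags <- vapply(fs, `[[`, "", "locus")
  rows <- list()
  for (i in seq_len(nrow(feats))) {
    f <- feats[i, ]
    if (f$locus_tag %in% fs_tags) {
      e <- fs[[match(f$locus_tag, fs_tags)]]
      sim <- e$split
      s2 <- shift(f$start)
      # reading-orientation offsets -> genome coordinates on the derived genome
      if (f$strand == "+") {
        p1 <- c(s2, s2 + sim$part1_len)
        p2 <- c(s2 + sim$part2_off, s2 + sim$new_len)
      } else {
        p1 <- c(s2 + sim$new_len - sim$part1_len, s2 + sim$new_len)
        p2 <- c(s2, s2 + sim$new_len - sim$part2_off)
      }
      rows[[length(rows) + 1L]] <- feature_table(
        locus_tag = paste0(f$locus_tag, "_1"), kind = "CDS",
        start = p1[1L], end = p1[2L], strand = f$strand,
        pseudo = FALSE, product_name = f$product_name)
      rows[[length(rows) + 1L]] <- feature_table(
        locus_tag = paste0(f$locus_tag, "_2"), kind = "CDS",
        start = p2[1L], end = p2[2L], strand = f$strand,
        pseudo = FALSE, product_name = f$product_name)
      next
    }
    strand <- f$strand
    fs_start <- f$start; fs_end <- f$end
    for (e in inv) {  # feature wholly inside an inverted interval
      if (f$start >= e$anc_start && f$end <= e$anc_end) {
        new_start <- e$anc_start + (e$anc_end - f$end)
        new_end <- e$anc_start + (e$anc_end - f$start)
        fs_start <- new_start; fs_end <- new_end
        strand <- if (strand == "+") "-" else "+"
        break
      }
    }
    rows[[length(rows) + 1L]] <- feature_table(
      locus_tag = f$locus_tag, kind = f$kind,
      start = shift(fs_start), end = shift(fs_end), strand = strand,
      pseudo = f$pseudo, product_name = f$product_name)
  }
  # genes planted inside carried strain-specific blocks
  for (e in carried) {
    if (is.null(e$features)) next
    base <- shift(e$anc_start)
    bf <- e$features
    for (i in seq_len(nrow(bf))) {
      rows[[length(rows) + 1L]] <- feature_table(
        locus_tag = bf$locus_tag[i], kind = bf$kind[i],
        start = base + bf$start[i], end = base + bf$end[i],
        strand = bf$strand[i], pseudo = bf$pseudo[i],
        product_name = bf$product_name[i])
    }
  }
  features <- if (length(rows)) do.call(rbind, rows) else feature_table()
  list(sequence = sequence, features = features, shift = shift)
}

build_truth <- function(ev, shift_a, shift_b) {
  rows <- lapply(ev, function(e) {
    ins_len <- nchar(e$payload)
    anc_len <- e$anc_end - e$anc_start
    span <- function(shift, is_carrier) {
      s <- shift(e$anc_start)
      if (e$type %in% c("mge_insertion", "tandem_cnv")) {
        # payload sits at the end of the anchor (TA site / ancestral array)
        s <- shift(e$anc_start) + anc_len
        if (is_carrier) c(s, s + ins_len) else c(s, s)
      } else if (e$type %in% c("block_indel", "one_base_insertion",
                               "frameshift_insertion")) {
        if (is_carrier) c(s, s + ins_len) else c(s, s)
      } else if (e$type %in% c("one_base_deletion", "frameshift_deletion")) {
        if (is_carrier) c(s, s) else c(s, s + anc_len)
      } else {
        c(s, s + anc_len)   # snp, inversion: in-place replacement
      }
    }
    sa <- span(shift_a, e$carrier == "a")
    sb <- span(shift_b, e$carrier == "b")
    data.frame(event_id = e$event_id, type = e$type, carrier = e$carrier,
               anc_start = e$anc_start, anc_end = e$anc_end,
               a_start = sa[1L], a_end = sa[2L],
               b_start = sb[1L], b_end = sb[2L],
               payload = e$payload,
               unit = if (is.null(e$unit)) NA_character_ else e$unit,
               anc_copies = if (is.null(e$anc_copies)) NA_integer_ else e$anc_copies,
               carrier_copies = if (is.null(e$carrier_copies)) NA_integer_ else e$carrier_copies,
               locus = if (is.null(e$locus)) NA_character_ else e$locus)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(event_id = integer(), type = character(), carrier = character(),
               anc_start = integer(), anc_end = integer(),
               a_start = integer(), a_end = integer(),
               b_start = integer(), b_end = integer(), payload = character(),
               unit = character(), anc_copies = integer(),
               carrier_copies = integer(), locus = character())
  out <- out[order(out$anc_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf("<synthetic_pair> %s (%s bp) / %s (%s bp), %d seeded event(s)\n",
              x$a$id, format(x$a$length, big.mark = ","),
              x$b$id, format(x$b$length, big.mark = ","), nrow(x$truth)))
  print(table(x$truth$type))
  invisible(x)
}

#' Generate a synthetic pair in one call
#'
#' @param spec a [mutation_spec()].
#' @return A `synthetic_pair`; see [mutate_pair()].
#' @export
generate_pair <- function(spec = mutation_spec()) {
  mutate_pair(generate_ancestor(spec), spec)
}

#' Write a synthetic pair to disk as FASTA + GenBank + truth TSV
#'
#' Emits `a.fasta`, `b.fasta`, `a.gbk`, `b.gbk` and `truth.tsv` (with the
#' seed recorded in a header comment). Output bytes are deterministic for a
#' fixed spec.
#'
#' @param pair a `synthetic_pair`.
#' @param out_dir output directory (created if missing).
#' @return Named character vector of the written paths, invisibly.
#' @export
emit_fixture <- function(pair, out_dir) {
  stopifnot(inherits(pair, "synthetic_pair"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(a_fasta = file.path(out_dir, "a.fasta"),
             b_fasta = file.path(out_dir, "b.fasta"),
             a_gbk = file.path(out_dir, "a.gbk"),
             b_gbk = file.path(out_dir, "b.gbk"),
             truth = file.path(out_dir, "truth.tsv"))
  write_genome_fasta(pair$a, paths["a_fasta"])
  write_genome_fasta(pair$b, paths["b_fasta"])
  write_genome_genbank(pair$a, paths["a_gbk"])
  write_genome_genbank(pair$b, paths["b_gbk"])
  con <- file(paths["truth"], "w")
  writeLines(sprintf("# synthetic pair truth table; seed=%d", pair$spec$seed), con)
  write.table(pair$truth, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  invisible(paths)
}
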
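# io_formats: genome records, feature tables, and the standard file formats
# the pipeline touches. Internal coordinates are 0-based half-open on the
# forward strand throughout; conversion to 1-based inclusive happens only at
# the GenBank/GFF3 report boundary.

#' Construct a genome record
#'
#' The shared container for one chromosome: an accession-like id, the
#' uppercase sequence, a circularity flag and an optional feature table.
#' Circular genomes are handled linearised at the record's given origin; the
#' comparison machinery does not wrap across the origin.
#'
#' @param id accession-like string.
#' @param sequence DNA string over A/C/G/T/N (lowercase is upper-cased).
#' @param circular logical; purely descriptive downstream.
#' @param features data.frame of features, see [feature_table()].
#' @return An object of class `genome_record` with fields `id`, `sequence`,
#'   `length`, `circular`, `features`.
#' @export
genome_record <- function(id, sequence, circular = FALSE, features = feature_table()) {
  sequence <- validate_dna(sequence, paste0("genome '", id, "'"))
  features <- validate_features(features, nchar(sequence))
  structure(
    list(id = as.character(id), sequence = sequence, length = nchar(sequence),
         circular = isTRUE(circular), features = features),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp%s, %d feature(s)\n",
              x$id, format(x$length, big.mark = ","),
              if (x$circular) " (circular)" else "", nrow(x$features)))
  invisible(x)
}

#' Build an empty or populated feature table
#'
#' Features use 0-based half-open coordinates on the forward strand.
#' `kind` is one of `CDS`, `rRNA`, `other`.
#'
#' @param locus_tag,kind,start,end,strand,pseudo,product_name parallel vectors.
#' @return A data.frame with one row per feature.
#' @export
feature_table <- function(locus_tag = character(), kind = character(),
                          start = integer(), end = integer(),
                          strand = character(), pseudo = logical(),
                          product_name = character()) {
  data.frame(locus_tag = as.character(locus_tag), kind = as.character(kind),
             start = as.integer(start), end = as.integer(end),
             strand = as.character(strand), pseudo = as.logical(pseudo),
             product_name = as.character(product_name),
             stringsAsFactors = FALSE)
}

validate_features <- function(features, genome_length) {
  required <- c("locus_tag", "kind", "start", "end", "strand", "pseudo", "product_name")
  if (!is.data.frame(features) || !all(required %in% names(features))) {
    stop("features must be a data.frame built by feature_table()", call. = FALSE)
  }
  if (nrow(features) == 0L) return(features)
  if (anyDuplicated(features$locus_tag)) {
    stop("duplicate locus_tag in feature table", call. = FALSE)
  }
  with(features, {
    if (any(start < 0L) || any(end > genome_length) || any(start >= end)) {
      stop("feature coordinates violate 0 <= start < end <= genome length",
           call. = FALSE)
    }
    if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'", call. = FALSE)
    if (!all(kind %in% c("CDS", "rRNA", "other"))) {
      stop("feature kind must be CDS, rRNA or other", call. = FALSE)
    }
  })
  features[order(features$start, features$end), , drop = FALSE]
}

#' Read a genome from FASTA or GenBank
#'
#' FASTA parsing goes through [Biostrings::readDNAStringSet()]; GenBank flat
#' files are read by a minimal internal parser that captures the LOCUS line
#' (length, circular topology), CDS and rRNA features with their
#' `locus_tag`, `product` and `pseudo` qualifiers, and the ORIGIN sequence.
#' GenBank 1-based inclusive feature spans are converted to the internal
#' 0-based half-open convention.
#'
#' @param path file path.
#' @param format `"fasta"` or `"genbank"`; default guesses from the extension.
#' @return A single [genome_record()], or a list of them for multi-record files.
#' @export
read_genome <- function(path, format = c("auto", "fasta", "genbank")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(gb|gbk|gbff|genbank)$", path, ignore.case = TRUE))
      "genbank" else "fasta"
  }
  recs <- if (format == "fasta") read_genome_fasta(path) else read_genome_genbank(path)
  if (length(recs) == 1L) recs[[1L]] else recs
}

read_genome_fasta <- function(path) {
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("no sequence records in ", path, call. = FALSE)
  lapply(seq_along(set), function(i) {
    id <- sub("\\s.*$", "", names(set)[i])
    genome_record(id, as.character(set[[i]]))
  })
}

read_genome_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^LOCUS", lines)
  if (length(starts) == 0L) stop("malformed GenBank '", path,
                                 "': no LOCUS line", call. = FALSE)
  ends <- grep("^//", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  lapply(seq_along(starts), function(i) {
    parse_genbank_record(lines[starts[i]:ends[i]], path, starts[i])
  })
}

parse_genbank_record <- function(lines, path, offset) {
  locus <- strsplit(trimws(lines[1L]), "\\s+")[[1L]]
  id <- if (length(locus) >= 2L) locus[2L] else "unknown"
  circular <- any(grepl("circular", lines[1L], ignore.case = TRUE))

  origin_at <- grep("^ORIGIN", lines)
  if (length(origin_at) != 1L) {
    stop("malformed GenBank record '", id, "' in ", path,
         " (line ", offset, "): expected one ORIGIN section", call. = FALSE)
  }
  seq_lines <- lines[(origin_at + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) {
    stop("empty sequence in GenBank record '", id, "' of ", path, call. = FALSE)
  }

  feat_at <- grep("^FEATURES", lines)
  features <- feature_table()
  if (length(feat_at) == 1L && origin_at > feat_at + 1L) {
    features <- parse_genbank_features(lines[(feat_at + 1L):(origin_at - 1L)],
                                       nchar(sequence), id)
  }
  genome_record(id, sequence, circular = circular, features = features)
}

parse_genbank_features <- function(lines, genome_length, id) {
  # feature headers sit at column 6, qualifiers at column 22
  is_header <- grepl("^     \\S", lines)
  idx <- which(is_header)
  out <- list()
  for (j in seq_along(idx)) {
    from <- idx[j]
    to <- if (j < length(idx)) idx[j + 1L] - 1L else length(lines)
    key <- sub("^\\s+", "", sub("^(\\s+\\S+).*$", "\\1", lines[from]))
    if (!key %in% c("CDS", "rRNA")) next
    block <- lines[from:to]
    loc <- sub("^\\s+\\S+\\s+", "", block[1L])
    qual_start <- grep("^\\s+/", block)
    if (length(qual_start)) {
      extra <- setdiff(seq_len(length(block))[-1L], seq(qual_start[1L], length(block)))
      if (length(extra)) loc <- paste0(loc, gsub("\\s", "", paste(block[extra], collapse = "")))
    } else if (length(block) > 1L) {
      loc <- paste0(loc, gsub("\\s", "", paste(block[-1L], collapse = "")))
    }
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- regmatches(loc, gregexpr("[0-9]+", loc))[[1L]]
    if (length(nums) < 2L) next
    start1 <- as.integer(nums[1L]); end1 <- as.integer(nums[length(nums)])
    quals <- paste(block[grep("^\\s+/", block)[1L]:length(block)], collapse = " ")
    grab <- function(name) {
      m <- regmatches(quals, regexpr(paste0("/", name, '="[^"]*"'), quals))
      if (length(m)) sub('"$', "", sub(paste0('^/', name, '="'), "", m)) else NA_character_
    }
    tag <- grab("locus_tag")
    if (is.na(tag)) tag <- sprintf("%s_f%04d", id, length(out) + 1L)
    product <- grab("product")
    if (is.na(product)) product <- ""
    pseudo <- grepl("/pseudo(\\s|$|=)", quals)
    out[[length(out) + 1L]] <- feature_table(
      locus_tag = tag, kind = key,
      start = start1 - 1L, end = end1,  # 1-based inclusive -> 0-based half-open
      strand = strand, pseudo = pseudo, product_name = product)
  }
  if (length(out) == 0L) return(feature_table())
  validate_features(do.call(rbind, out), genome_length)
}

#' Write a genome record to FASTA
#'
#' @param genome a [genome_record()].
#' @param path output path.
#' @param width line width for the sequence.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_record"))
  n <- genome$length
  starts <- seq(1L, n, by = width)
  lines <- c(paste0(">", genome$id),
             substring(genome$sequence, starts, pmin(starts + width - 1L, n)))
  writeLines(lines, path)
  invisible(path)
}

#' Write a genome record as a GenBank flat file
#'
#' Emits the subset of GenBank the pipeline consumes: LOCUS with length and
#' topology, CDS/rRNA features with `locus_tag`, `product` and `pseudo`
#' qualifiers (converted back to 1-based inclusive spans), and ORIGIN.
#' Output is deterministic: identical records yield byte-identical files.
#'
#' @inheritParams write_genome_fasta
#' @export
write_genome_genbank <- function(genome, path) {
  stopifnot(inherits(genome, "genome_record"))
  topo <- if (genome$circular) "circular" else "linear"
  out <- c(sprintf("LOCUS       %s %d bp    DNA     %s   BCT",
                   genome$id, genome$length, topo),
           sprintf("DEFINITION  %s.", genome$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", genome$length))
  f <- genome$features
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      span <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
      if (f$strand[i] == "-") span <- sprintf("complement(%s)", span)
      out <- c(out,
               sprintf("     %-16s%s", f$kind[i], span),
               sprintf('                     /locus_tag="%s"', f$locus_tag[i]))
      if (nzchar(f$product_name[i])) {
        out <- c(out, sprintf('                     /product="%s"', f$product_name[i]))
      }
      if (f$pseudo[i]) out <- c(out, "                     /pseudo")
    }
  }
  out <- c(out, "ORIGIN")
  starts <- seq(1L, genome$length, by = 60L)
  for (s in starts) {
    chunk <- substr(genome$sequence, s, min(s + 59L, genome$length))
    blocks <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", s, tolower(paste(blocks, collapse = " "))))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

#' Write a pipeline result table to TSV, GFF3 or BED
#'
#' TSV emits the table as-is with a header; GFF3 and BED convert the internal
#' 0-based half-open `start`/`end` columns to their standard conventions
#' (GFF3 1-based inclusive, BED 0-based half-open). Rows are sorted by
#' coordinates so identical inputs yield byte-identical files.
#'
#' @param result a data.frame; for gff3/bed it must carry `start` and `end`
#'   columns (plus `seqid`, and optionally `strand`, `name`, `type`).
#' @param path output path.
#' @param format one of `"tsv"`, `"gff3"`, `"bed"`.
#' @export
write_report <- function(result, path, format = c("tsv", "gff3", "bed")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(result))
  if (format == "tsv") {
    ord <- do.call(order, unname(as.list(result)))
    write.table(result[ord, , drop = FALSE], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  need <- c("seqid", "start", "end")
  if (nrow(result) > 0 && !all(need %in% names(result))) {
    stop("gff3/bed output needs seqid/start/end columns", call. = FALSE)
  }
  result <- result[order(result$seqid, result$start, result$end), , drop = FALSE]
  strand <- if ("strand" %in% names(result)) result$strand else rep(".", nrow(result))
  name <- if ("name" %in% names(result)) result$name else rep(".", nrow(result))
  type <- if ("type" %in% names(result)) result$type else rep("region", nrow(result))
  if (format == "gff3") {
    lines <- "##gff-version 3"
    if (nrow(result)) {
      lines <- c(lines, sprintf("%s\tpairseg\t%s\t%d\t%d\t.\t%s\t.\tName=%s",
                                result$seqid, type, result$start + 1L,
                                result$end, strand, name))
    }
  } else {
    lines <- if (nrow(result)) {
      sprintf("%s\t%d\t%d\t%s\t0\t%s", result$seqid, result$start,
              result$end, name, strand)
    } else character()
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read back a TSV written by [write_report()]
#'
#' @param path file path.
#' @return A data.frame.
#' @export
read_report_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, comment.char = "#")
}

#' Convert between internal and report coordinate conventions
#'
#' Internal coordinates are 0-based half-open; reports use 1-based inclusive.
#' `to_report()` and `to_internal()` are mutually inverse.
#'
#' @param start,end interval in the source convention.
#' @return A list with converted `start` and `end`.
#' @export
to_report <- function(start, end) list(start = start + 1L, end = end)

#' @rdname to_report
#' @export
to_internal <- function(start, end) list(start = start - 1L, end = end)
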
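# Full-scale reproduction against the published genome sequences. The three
# chromosomes are not bundled with the package (about 17 MB of sequence);
# they must be downloaded once by the user and placed in a directory as
# plain FASTA or GenBank files named by accession.

#' Expected reference genome files
#'
#' The full-scale comparison uses three published *Photorhabdus luminescens*
#' chromosomes: BX470251 (the originally published TT01 genome), CP024901
#' (the re-sequenced TT01m genome) and CP024900 (the DJC genome). Files may
#' be FASTA (`<accession>.fasta`) or GenBank (`<accession>.gbk`); GenBank
#' input additionally enables the rpoB comparison.
#'
#' @param dir directory holding the files.
#' @return data.frame with `accession`, `path` (NA when absent), `format`.
#' @export
reference_genome_files <- function(dir = getOption("pairseg.reference_dir",
                                                   "reference_genomes")) {
  acc <- c("BX470251", "CP024901", "CP024900")
  find_one <- function(a) {
    for (ext in c(".gbk", ".gb", ".gbff", ".fasta", ".fa", ".fna")) {
      p <- file.path(dir, paste0(a, ext))
      if (file.exists(p)) return(p)
    }
    NA_character_
  }
  paths <- vapply(acc, find_one, "")
  data.frame(accession = acc, path = unname(paths),
             format = ifelse(grepl("\\.g", basename(paths)), "genbank", "fasta"))
}

#' Reproduce the published strain comparison at full scale
#'
#' Runs the complete pipeline on the three reference chromosomes: the exact-
#' match mapper on BX470251 vs CP024901 (two assemblies of the same strain,
#' expected to differ at a handful of positions), and the three-pass
#' segmentation plus divergence statistics on CP024901 vs CP024900 (two
#' independent isolates). With annotated (GenBank) input the rpoB
#' coding-sequence comparison is included.
#'
#' @param dir directory with the reference files; see
#'   [reference_genome_files()].
#' @return list: `tt01_vs_tt01m` (typed difference table and its row count),
#'   `segmentation` (the `pairseg_segmentation`), `stats`
#'   ([segmentation_stats()] of it), and `rpob` (a `cds_comparison` or NULL).
#' @export
reproduce_reference_comparison <- function(dir = getOption("pairseg.reference_dir",
                                                           "reference_genomes")) {
  files <- reference_genome_files(dir)
  missing <- files$accession[is.na(files$path)]
  if (length(missing)) {
    stop("reference genomes not found in '", dir, "': ",
         paste(missing, collapse = ", "),
         " (download the accessions and place them there as FASTA or GenBank)",
         call. = FALSE)
  }
  g <- lapply(seq_len(nrow(files)), function(i)
    read_genome(files$path[i], files$format[i]))
  names(g) <- files$accession

  diffs <- type_differences(decompose(g$BX470251, g$CP024901, min_run = 20L))
  seg <- compare_genomes(g$CP024901, g$CP024900)
  stats <- segmentation_stats(seg)

  rpob <- NULL
  has_cds <- vapply(g, function(x) any(x$features$kind == "CDS"), TRUE)
  if (all(has_cds[c("CP024901", "CP024900")])) {
    find_rpob <- function(genome) {
      f <- genome$features
      i <- grep("RNA polymerase.*beta['s]*[^']|rpoB", f$product_name,
                ignore.case = TRUE)
      i <- setdiff(i, grep("beta'", f$product_name, fixed = TRUE))
      if (length(i)) cds_sequence(genome, f[i[1L], ]) else NULL
    }
    nt1 <- find_rpob(g$CP024901); nt2 <- find_rpob(g$CP024900)
    if (!is.null(nt1) && !is.null(nt2) && nchar(nt1) == nchar(nt2)) {
      rpob <- compare_cds(nt1, nt2)
    }
  }
  list(tt01_vs_tt01m = list(diffs = diffs, n_differences = nrow(diffs)),
       segmentation = seg, stats = stats, rpob = rpob)
}
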
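#' Write simulation outputs to standard formats
#'
#' `write_sim_fasta()` writes the host and transgene contig sequences of an
#' insertion allele to FASTA. `write_sim_fastq()` writes the reads of a
#' [simulate_paired_reads()] run (with `emit_sequences = TRUE`) as a pair of
#' FASTQ files (uniform maximal qualities; no quality-score realism).
#' `write_sim_sam()` writes the truth alignments as a minimal valid SAM file
#' (1-based coordinates, header `@SQ` lines from the contig table).
#'
#' @param allele An `insertion_allele`.
#' @param sim A `read_sim`.
#' @param path,prefix Output file path, or path prefix for the FASTQ pair
#'   (`<prefix>_1.fastq`, `<prefix>_2.fastq`).
#' @return The written path(s), invisibly.
#' @name sim_io
NULL

#' @rdname sim_io
#' @export
write_sim_fasta <- function(allele, path) {
  stopifnot(inherits(allele, "insertion_allele"))
  seqs <- c(
    setNames(allele$ref$sequence, allele$ref$name),
    setNames(allele$units$sequence, allele$units$name)
  )
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' @rdname sim_io
#' @export
write_sim_fastq <- function(sim, prefix) {
  stopifnot(inherits(sim, "read_sim"))
  if (is.null(sim$reads)) {
    abort("no sequences in `sim`; rerun with `emit_sequences = TRUE`")
  }
  paths <- paste0(prefix, "_", 1:2, ".fastq")
  for (m in 1:2) {
    r <- sim$reads %>% filter(.data$mate == m)
    qual <- strrep("I", nchar(r$seq[1]))
    lines <- as.vector(rbind(
      paste0("@", r$read_id, "/", m), r$seq, "+", qual
    ))
    readr::write_lines(lines, paths[m])
  }
  invisible(paths)
}

#' @rdname sim_io
#' @export
write_sim_sam <- function(sim, path) {
  stopifnot(inherits(sim, "read_sim"))
  aln <- sim$alignments
  header <- c(
    "@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", sim$contigs$contig,
            as.integer(sim$contigs$length))
  )
  flag <- 1L + # paired
    ifelse(aln$proper, 2L, 0L) +
    ifelse(aln$mapped, 0L, 4L) +
    ifelse(aln$mate_mapped, 0L, 8L) +
    ifelse(aln$strand == "-", 16L, 0L) +
    ifelse(aln$mate_mapped & aln$strand == "+", 32L, 0L) +
    ifelse(aln$mate == 1L, 64L, 128L)
  rl <- sim$params$read_len
  body <- sprintf(
    "%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t*\t*",
    aln$read_id, flag,
    ifelse(aln$mapped, aln$contig, "*"),
    ifelse(aln$mapped, aln$pos, 0L),
    ifelse(aln$mapped, 60L, 0L),
    ifelse(aln$mapped, paste0(rl, "M"), "*"),
    ifelse(aln$mate_mapped,
           ifelse(!is.na(aln$mate_contig) & !is.na(aln$contig) &
                    aln$mate_contig == aln$contig, "=", aln$mate_contig),
           "*"),
    ifelse(aln$mate_mapped, aln$mate_pos, 0L),
    ifelse(is.na(aln$isize), 0L, aln$isize)
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}

#' Read alignment records from a SAM file
#'
#' Parses a SAM text file into the alignment tibble consumed by
#' [compute_depth()] and [collect_chimeric_pairs()]. Only the pair-level
#' fields used by the insertion mapper are retained. Externally aligned
#' files are accepted as long as they are SAM text; convert BAM with
#' `samtools view -h`.
#'
#' @param path Path to a SAM file.
#' @return A tibble with the same columns as `read_sim$alignments`, plus an
#'   attribute `"contigs"` carrying the `@SQ` contig table.
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  contigs <- tibble(
    contig = stringr::str_match(sq, "SN:([^\\t]+)")[, 2],
    length = as.numeric(stringr::str_match(sq, "LN:(\\d+)")[, 2])
  )
  f <- stringr::str_split_fixed(body, "\t", 12)
  flag <- as.integer(f[, 2])
  aln <- tibble(
    read_id = f[, 1],
    mate = ifelse(bitwAnd(flag, 64L) > 0, 1L, 2L),
    contig = ifelse(f[, 3] == "*", NA_character_, f[, 3]),
    pos = ifelse(f[, 4] == "0", NA_integer_, as.integer(f[, 4])),
    strand = ifelse(bitwAnd(flag, 16L) > 0, "-", "+"),
    mate_contig = dplyr::case_when(
      f[, 7] == "*" ~ NA_character_,
      f[, 7] == "=" ~ f[, 3],
      TRUE ~ f[, 7]
    ),
    mate_pos = ifelse(f[, 8] == "0", NA_integer_, as.integer(f[, 8])),
    isize = ifelse(f[, 9] == "0", NA_integer_, as.integer(f[, 9])),
    mapped = bitwAnd(flag, 4L) == 0,
    mate_mapped = bitwAnd(flag, 8L) == 0,
    proper = bitwAnd(flag, 2L) > 0
  )
  attr(aln, "contigs") <- contigs
  aln
}

#' Read and write cohort, track and point-set tables
#'
#' Thin TSV readers/writers for the tabular inputs of the phenotype and
#' migration modules: cohorts (`id`, `sex`, `age_group`,
#' `ganglionic_fraction`, `megacolon`), tracks (`cell`, `t`, `x`, `y`) and
#' 2-D point sets (`x`, `y`).
#'
#' @param x A data frame to write.
#' @param path File path.
#' @return `read_*` return tibbles; `write_*` return `path` invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_cohort <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_df_cols(out, c("sex", "ganglionic_fraction", "megacolon"))
  out
}

#' @rdname table_io
#' @export
read_tracks <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  assert_df_cols(out, c("cell", "t", "x", "y"))
  out
}

#' @rdname table_io
#' @export
write_table_tsv <- function(x, path) {
  readr::write_tsv(x, path)
  invisible(path)
}
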
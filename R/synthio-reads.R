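#' Simulate paired-end reads from a diploid insertion genome
#'
#' Samples sequencing fragments uniformly from a diploid genome carrying a
#' transgene insertion allele ([build_insertion_allele()]) and emits truth
#' alignment records: each read is assigned the contig and 1-based position
#' it would map to. Reads fully inside the transgene array map to the
#' corresponding transgene unit contig; reads fully inside host segments
#' (including either copy of the target-site duplication) map to the host
#' chromosome; a read straddling a junction between segments is emitted
#' unmapped while its mate keeps its assignment. Pairs whose mates land on
#' different contigs (host vs transgene) are the chimeric, non-proper pairs
#' that downstream breakpoint calling consumes.
#'
#' The number of pairs is `coverage * total_length / (4 * read_len)`, where
#' `total_length` sums the sampled allele copies (two for a diploid), so
#' `coverage` is per haploid genome. Fragment lengths are Gaussian
#' `(insert_mean, insert_sd)` truncated to `[2 * read_len, 2 * insert_mean]`.
#'
#' @param genome An `insertion_allele` (expanded to two allele copies
#'   according to its zygosity), a `reference_genome`, or a character vector
#'   of allele sequences (used as given, e.g. a single string is haploid).
#' @param coverage Fold coverage (> 0).
#' @param read_len Read length in bases.
#' @param insert_mean,insert_sd Fragment (insert) length distribution, bases.
#' @param error_rate Per-base uniform substitution probability (applied only
#'   when sequences are emitted).
#' @param seed Integer seed or `NULL`.
#' @param emit_sequences If `TRUE`, read sequences are extracted from the
#'   allele sequences (reverse-complemented for the reverse mate) and kept in
#'   the result for FASTQ output. Off by default: depth and breakpoint
#'   inference only need the truth alignments.
#' @return An object of class `read_sim`: list with
#'   * `alignments`: tibble, one row per read (`read_id`, `mate`, `contig`,
#'     `pos`, `strand`, `mate_contig`, `mate_pos`, `isize`, `mapped`,
#'     `mate_mapped`, `proper`),
#'   * `fragments`: tibble of true sampled fragments (`allele`, `start`,
#'     `frag_len`) in allele coordinates,
#'   * `reads`: tibble of sequences (if requested),
#'   * `params`, `truth`, `contigs` (contig lengths).
#' @examples
#' ref <- make_reference(20000, seed = 1)
#' sim <- simulate_paired_reads(ref, coverage = 5, seed = 2)
#' nrow(sim$alignments)
#' @export
simulate_paired_reads <- function(genome, coverage, read_len = 100,
                                  insert_mean = 400, insert_sd = 35,
                                  error_rate = 0, seed = NULL,
                                  emit_sequences = FALSE) {
  if (coverage <= 0) abort("`coverage` must be positive")
  if (insert_mean <= 2 * read_len) {
    abort("`insert_mean` must exceed twice the read length")
  }
  local_seed(seed)

  alleles <- expand_alleles(genome)
  lens <- purrr::map_int(alleles, function(a) nchar(a$sequence))
  total_len <- sum(as.numeric(lens))
  n_pairs <- round(coverage * total_len / (4 * read_len))
  # apportion pairs to allele copies by length (largest-remainder rounding)
  share <- n_pairs * lens / total_len
  n_alloc <- floor(share)
  rem <- n_pairs - sum(n_alloc)
  if (rem > 0) {
    top <- order(share - n_alloc, decreasing = TRUE)[seq_len(rem)]
    n_alloc[top] <- n_alloc[top] + 1
  }

  per_allele <- purrr::imap(alleles, function(a, i) {
    n <- n_alloc[[i]]
    if (n == 0) return(NULL)
    L <- lens[[i]]
    frag <- draw_fragment_lengths(n, insert_mean, insert_sd, read_len)
    start <- 1L + floor(runif(n) * (L - frag + 1))
    tibble(allele = i, start = as.integer(start), frag_len = as.integer(frag))
  })
  fragments <- bind_rows(per_allele)
  fragments$read_id <- sprintf("frag_%07d", seq_len(nrow(fragments)))

  # two reads per fragment: forward at the fragment start, reverse at its end
  reads <- bind_rows(
    fragments %>% mutate(mate = 1L, rstart = .data$start, strand = "+"),
    fragments %>% mutate(
      mate = 2L, rstart = .data$start + .data$frag_len - read_len, strand = "-"
    )
  )

  seg_tabs <- purrr::map(alleles, "segments")
  mapped <- purrr::map(seq_along(alleles), function(i) {
    r <- reads %>% filter(.data$allele == i)
    map_reads_to_segments(r$rstart, read_len, seg_tabs[[i]])
  })
  reads <- reads %>%
    arrange(.data$allele) %>%
    dplyr::bind_cols(bind_rows(mapped))

  aln <- reads %>%
    select("read_id", "mate", "contig", "pos", "strand", "allele", "rstart",
           "frag_len") %>%
    mutate(mapped = !is.na(.data$contig))
  mate_info <- aln %>%
    mutate(mate = 3L - .data$mate) %>%
    select("read_id", "mate",
           mate_contig = "contig", mate_pos = "pos", mate_mapped = "mapped")
  aln <- aln %>%
    left_join(mate_info, by = c("read_id", "mate")) %>%
    mutate(
      proper = .data$mapped & .data$mate_mapped &
        .data$contig == .data$mate_contig,
      isize = ifelse(.data$proper,
                     ifelse(.data$strand == "+", .data$frag_len,
                            -.data$frag_len), NA_integer_)
    ) %>%
    select("read_id", "mate", "contig", "pos", "strand", "mate_contig",
           "mate_pos", "isize", "mapped", "mate_mapped", "proper")

  seqs <- NULL
  if (emit_sequences) {
    seqs <- extract_read_sequences(reads, alleles, read_len, error_rate)
  }

  contigs <- contig_lengths(alleles)
  structure(
    list(
      alignments = aln, fragments = fragments, reads = seqs,
      contigs = contigs,
      params = list(
        coverage = coverage, read_len = read_len, insert_mean = insert_mean,
        insert_sd = insert_sd, error_rate = error_rate, n_pairs = n_pairs
      ),
      truth = attr(alleles, "truth")
    ),
    class = "read_sim"
  )
}

#' @export
print.read_sim <- function(x, ...) {
  cat(sprintf(
    "<read_sim> %s pairs, %s bp reads, %s contigs\n",
    format(x$params$n_pairs, big.mark = ","), x$params$read_len,
    nrow(x$contigs)
  ))
  invisible(x)
}

# Normalize the genome argument into a list of allele copies, each a list
# (sequence, segments). An insertion allele expands to two copies: hom ->
# mutant/mutant, het -> mutant/reference.
expand_alleles <- function(genome) {
  one_host <- function(seq, name) {
    list(
      sequence = seq,
      segments = tibble(
        start = 1, end = nchar(seq), contig = name, contig_start = 1,
        class = "host", unit = NA_character_
      )
    )
  }
  if (inherits(genome, "insertion_allele")) {
    mut <- list(sequence = genome$sequence, segments = genome$segments)
    other <- if (genome$truth$zygosity == "hom") {
      mut
    } else {
      one_host(genome$ref$sequence, genome$ref$name)
    }
    out <- list(mut, other)
    attr(out, "truth") <- genome$truth
    return(out)
  }
  if (inherits(genome, "reference_genome")) {
    return(list(one_host(genome$sequence, genome$name)))
  }
  if (is.character(genome)) {
    nms <- names(genome) %||% paste0("seq", seq_along(genome))
    return(purrr::map2(unname(genome), nms, one_host))
  }
  abort("`genome` must be an insertion_allele, reference_genome or character")
}

draw_fragment_lengths <- function(n, insert_mean, insert_sd, read_len) {
  lo <- 2 * read_len
  hi <- 2 * insert_mean
  frag <- round(rnorm(n, insert_mean, insert_sd))
  bad <- which(frag < lo | frag > hi)
  while (length(bad) > 0) { # redraw, preserving the truncated-Gaussian shape
    frag[bad] <- round(rnorm(length(bad), insert_mean, insert_sd))
    bad <- bad[frag[bad] < lo | frag[bad] > hi]
  }
  frag
}

# Assign reads (1-based starts, fixed length) to contigs via the allele's
# segment map. Reads crossing a segment boundary are unmapped (junction
# spanning; pair-level evidence only, no soft clips).
map_reads_to_segments <- function(rstart, read_len, segments) {
  idx <- findInterval(rstart, segments$start)
  inside <- rstart + read_len - 1 <= segments$end[idx]
  tibble(
    contig = ifelse(inside, segments$contig[idx], NA_character_),
    pos = ifelse(
      inside,
      as.integer(segments$contig_start[idx] + (rstart - segments$start[idx])),
      NA_integer_
    )
  )
}

contig_lengths <- function(alleles) {
  purrr::map(alleles, function(a) {
    a$segments %>%
      group_by(.data$contig) %>%
      summarise(
        length = max(.data$contig_start + (.data$end - .data$start)),
        .groups = "drop"
      )
  }) %>%
    bind_rows() %>%
    group_by(.data$contig) %>%
    summarise(length = max(.data$length), .groups = "drop")
}

extract_read_sequences <- function(reads, alleles, read_len, error_rate) {
  seqs <- purrr::map(seq_along(alleles), function(i) {
    r <- reads %>% filter(.data$allele == i)
    s <- substring(alleles[[i]]$sequence, r$rstart, r$rstart + read_len - 1)
    tibble(read_id = r$read_id, mate = r$mate, strand = r$strand, seq = s)
  }) %>% bind_rows()
  rev_idx <- seqs$strand == "-"
  seqs$seq[rev_idx] <- revcomp(seqs$seq[rev_idx])
  if (error_rate > 0) {
    seqs$seq <- mutate_sequences(seqs$seq, error_rate)
  }
  seqs %>% select("read_id", "mate", "seq")
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(
    strsplit(x, "", fixed = TRUE),
    function(ch) paste(rev(ch), collapse = ""), character(1)
  ))
}

# uniform substitutions at rate `rate`; substituted base drawn from the
# three alternatives
mutate_sequences <- function(seqs, rate) {
  vapply(seqs, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(ch)) < rate)
    if (length(hit) > 0) {
      ch[hit] <- vapply(ch[hit], function(b) {
        sample(setdiff(c("A", "C", "G", "T"), b), 1)
      }, character(1))
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}
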
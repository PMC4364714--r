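#' Windowed, baseline-normalized read depth
#'
#' Counts mapped read starts in fixed windows per contig and normalizes each
#' window by the genome baseline, the median count over the host (autosomal)
#' windows. On unaffected host regions the normalized depth fluctuates
#' around 1; a homozygous tandem duplication shows as ~2, a heterozygous one
#' as ~1.5, and a transgene unit contig carrying many concatemer copies as a
#' depth close to the diploid copy number over two.
#'
#' @param alignments Alignment tibble (from `read_sim$alignments` or
#'   [read_sam()]); a `read_sim` may be passed directly. Only mapped reads
#'   are counted.
#' @param window Window size in bases (>= 100).
#' @param contigs Optional tibble (`contig`, `length`) used to lay out
#'   windows (so zero-coverage windows are kept). Defaults to the `read_sim`
#'   contig table, the `"contigs"` attribute of the alignments, or the
#'   maximum observed position per contig.
#' @param baseline_contig Contig(s) whose windows define the baseline.
#'   Defaults to the longest contig (the host chromosome).
#' @return A tibble of class `depth_profile` with columns `contig`, `start`,
#'   `end`, `n_reads`, `depth_norm`, and attributes `baseline`, `window`,
#'   `baseline_contig`.
#' @export
compute_depth <- function(alignments, window = 1000, contigs = NULL,
                          baseline_contig = NULL) {
  if (inherits(alignments, "read_sim")) {
    contigs <- contigs %||% alignments$contigs
    alignments <- alignments$alignments
  }
  assert_df_cols(alignments, c("contig", "pos", "mapped"))
  if (window < 100) abort("`window` must be >= 100 bases")
  aln <- alignments %>% filter(.data$mapped)
  if (nrow(aln) == 0) abort("no mapped reads in the alignment stream")
  contigs <- contigs %||% attr(alignments, "contigs") %||%
    (aln %>% group_by(.data$contig) %>%
       summarise(length = max(.data$pos), .groups = "drop"))

  grid <- contigs %>%
    mutate(n_win = pmax(1, ceiling(.data$length / window))) %>%
    tidyr::uncount(.data$n_win, .id = "win") %>%
    mutate(
      start = (.data$win - 1) * window + 1,
      end = pmin(.data$win * window, .data$length)
    ) %>%
    select("contig", "start", "end")

  counts <- aln %>%
    mutate(win = floor((.data$pos - 1) / window) + 1,
           start = (.data$win - 1) * window + 1) %>%
    count(.data$contig, .data$start, name = "n_reads")

  prof <- grid %>%
    left_join(counts, by = c("contig", "start")) %>%
    mutate(n_reads = dplyr::coalesce(.data$n_reads, 0L))

  baseline_contig <- baseline_contig %||%
    contigs$contig[which.max(contigs$length)]
  base_windows <- prof %>%
    filter(.data$contig %in% baseline_contig,
           .data$end - .data$start + 1 == window) # full windows only
  baseline <- median(base_windows$n_reads)
  if (!is.finite(baseline) || baseline <= 0) {
    abort("depth baseline is not positive; too few host reads")
  }
  prof <- prof %>% mutate(depth_norm = .data$n_reads / baseline)
  attr(prof, "baseline") <- baseline
  attr(prof, "window") <- window
  attr(prof, "baseline_contig") <- baseline_contig
  class(prof) <- c("depth_profile", class(prof))
  prof
}

#' Detect duplicated segments from a depth profile
#'
#' Scans each contig for maximal runs of consecutive windows whose
#' normalized depth falls inside `ratio_window`, and reports runs of at
#' least `min_length` bases as duplication calls, snapped to window
#' boundaries. The zygosity call follows the copy arithmetic of a diploid
#' host: a normalized depth near 2 means the segment is duplicated on both
#' alleles (4 copies / 2 alleles), near 1.5 on one (3 / 2).
#'
#' @param profile A `depth_profile`.
#' @param min_length Minimum call length in bases.
#' @param ratio_window Length-2 numeric: normalized-depth interval treated
#'   as duplicated.
#' @param het_hom_cut Normalized depth at or above which a call is labelled
#'   homozygous (default 1.75).
#' @param contig Contig(s) to scan; defaults to the profile's baseline
#'   (host) contig.
#' @return A tibble (possibly empty) with columns `contig`, `start`, `end`,
#'   `length`, `mean_depth`, `copy_ratio`, `zygosity`.
#' @export
detect_duplication <- function(profile, min_length = 10000,
                               ratio_window = c(1.3, 2.7),
                               het_hom_cut = 1.75, contig = NULL) {
  stopifnot(inherits(profile, "depth_profile"))
  contig <- contig %||% attr(profile, "baseline_contig")
  prof <- profile %>%
    filter(.data$contig %in% !!contig) %>%
    arrange(.data$contig, .data$start)

  empty <- tibble(
    contig = character(), start = numeric(), end = numeric(),
    length = numeric(), mean_depth = numeric(), copy_ratio = numeric(),
    zygosity = character()
  )
  if (nrow(prof) == 0) return(empty)

  calls <- prof %>%
    group_by(.data$contig) %>%
    group_modify(function(d, key) {
      dup <- d$depth_norm >= ratio_window[1] & d$depth_norm <= ratio_window[2]
      r <- rle(dup)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      keep <- which(r$values)
      if (length(keep) == 0) return(empty[, -1])
      purrr::map(keep, function(k) {
        w <- seq(starts[k], ends[k])
        tibble(
          start = d$start[w[1]], end = d$end[w[length(w)]],
          mean_depth = mean(d$depth_norm[w])
        )
      }) %>% bind_rows()
    }) %>%
    ungroup() %>%
    mutate(
      length = .data$end - .data$start + 1,
      copy_ratio = .data$mean_depth,
      zygosity = ifelse(.data$mean_depth >= het_hom_cut, "hom", "het")
    ) %>%
    filter(.data$length >= min_length) %>%
    select("contig", "start", "end", "length", "mean_depth", "copy_ratio",
           "zygosity")
  calls
}
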
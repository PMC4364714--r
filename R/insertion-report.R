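#' Estimate transgene copy number and total insertion size
#'
#' Converts the normalized read depth of each transgene unit contig into
#' copies per allele and sums `copies x unit length` into the total
#' insertion size per allele. A unit contig collecting reads from `c` array
#' copies on each of `k` carrier alleles has normalized depth
#' `c * k / 2` against the diploid host baseline, so
#' `copies per allele = depth * 2 / k` (`k = 2` for a homozygous insertion,
#' 1 for a heterozygous one). Because reads straddling the boundary between
#' adjacent array copies are not counted, the per-contig read count is
#' converted to depth over the `length - read_len + 1` mappable start
#' positions of the unit rather than its full length.
#'
#' Copy estimates are reported both raw and rounded to the nearest integer
#' (ties round half-up).
#'
#' @param profile A `depth_profile` containing the transgene contigs.
#' @param zygosity `"hom"` or `"het"`; may be omitted if `dup` carries a
#'   zygosity call.
#' @param unit_lengths Named numeric vector: transgene contig -> unit length
#'   in bases.
#' @param dup Optional duplication call used for `zygosity` and embedded in
#'   the report.
#' @param junctions Optional junction-call tibble embedded in the report.
#' @param read_len Read length used for the mappable-length correction.
#' @return An object of class `insertion_report`: list with `copies` (tibble
#'   `unit`, `unit_length`, `copies_raw`, `copies`), `total_size_raw`,
#'   `total_size` (per allele, bases), `zygosity`, `duplication`,
#'   `junctions`.
#' @export
estimate_copies_and_size <- function(profile, zygosity = NULL, unit_lengths,
                                     dup = NULL, junctions = NULL,
                                     read_len = 100) {
  stopifnot(inherits(profile, "depth_profile"))
  if (is.null(names(unit_lengths)) || length(unit_lengths) == 0) {
    abort("`unit_lengths` must be a named vector of transgene contig lengths")
  }
  missing <- setdiff(names(unit_lengths), unique(profile$contig))
  if (length(missing) > 0) {
    abort(sprintf("transgene contig(s) absent from profile: %s",
                  paste(missing, collapse = ", ")))
  }
  zygosity <- zygosity %||% (if (!is.null(dup) && nrow(dup) == 1) dup$zygosity)
  if (is.null(zygosity)) {
    abort("zygosity unknown: supply `zygosity` or a duplication call")
  }
  zygosity <- match.arg(zygosity, c("hom", "het"))
  carriers <- if (zygosity == "hom") 2 else 1

  baseline <- attr(profile, "baseline")
  window <- attr(profile, "window")
  per_base_rate <- baseline / window # diploid host read starts per base

  copies <- tibble(
    unit = names(unit_lengths),
    unit_length = as.numeric(unit_lengths)
  ) %>%
    left_join(
      profile %>%
        group_by(unit = .data$contig) %>%
        summarise(n_reads = sum(.data$n_reads), .groups = "drop"),
      by = "unit"
    ) %>%
    mutate(
      n_reads = dplyr::coalesce(.data$n_reads, 0L),
      mappable = pmax(.data$unit_length - read_len + 1, 1),
      depth_norm = .data$n_reads / .data$mappable / per_base_rate,
      copies_raw = .data$depth_norm * 2 / carriers,
      copies = round_half_up(.data$copies_raw)
    ) %>%
    select("unit", "unit_length", "depth_norm", "copies_raw", "copies")

  structure(
    list(
      copies = copies,
      total_size_raw = sum(copies$copies_raw * copies$unit_length),
      total_size = sum(copies$copies * copies$unit_length),
      zygosity = zygosity,
      duplication = dup,
      junctions = junctions
    ),
    class = "insertion_report"
  )
}

#' @export
print.insertion_report <- function(x, ...) {
  cat(sprintf(
    "<insertion_report> %s insertion, ~%.0f kb per allele (%s)\n",
    x$zygosity, x$total_size_raw / 1000,
    paste(sprintf("%s x%d", x$copies$unit, x$copies$copies), collapse = ", ")
  ))
  if (!is.null(x$duplication) && nrow(x$duplication) == 1) {
    cat(sprintf(
      "  target-site duplication: %s:%s-%s (%.1f kb, depth %.2f)\n",
      x$duplication$contig, format(x$duplication$start, big.mark = ","),
      format(x$duplication$end, big.mark = ","),
      x$duplication$length / 1000, x$duplication$mean_depth
    ))
  }
  invisible(x)
}

#' @rdname estimate_copies_and_size
#' @param x An `insertion_report`.
#' @param ... Unused.
#' @method tidy insertion_report
#' @export
tidy.insertion_report <- function(x, ...) {
  x$copies %>% mutate(zygosity = x$zygosity)
}

#' @rdname estimate_copies_and_size
#' @method glance insertion_report
#' @export
glance.insertion_report <- function(x, ...) {
  tibble(
    zygosity = x$zygosity,
    total_size_raw = x$total_size_raw,
    total_size = x$total_size,
    dup_length = if (!is.null(x$duplication) && nrow(x$duplication) == 1) {
      x$duplication$length
    } else {
      NA_real_
    },
    bp_left = if (!is.null(x$junctions)) x$junctions$breakpoint[1] else NA_real_,
    bp_right = if (!is.null(x$junctions)) x$junctions$breakpoint[2] else NA_real_
  )
}

#' Genotype animals from semi-quantitative band densities
#'
#' Converts gel band densitometry into transgenic allele counts: a
#' transgene-specific amplicon signal is normalized to a chromosomal
#' amplicon outside the duplicated region and compared with the same ratio
#' measured in a known heterozygote. Allele count =
#' `round((tg / chr) / calibration)` (half-up); 0, 1 and 2 map to wild-type,
#' heterozygous and homozygous.
#'
#' @param bands A data frame with columns `tg_signal` and `chr_signal`
#'   (non-negative densities; `chr_signal` > 0), one row per animal.
#' @param het_calibration_ratio The `tg/chr` ratio of a known heterozygote.
#' @return The input with added columns `ratio`, `allele_count`, `genotype`.
#' @examples
#' bands <- tibble::tibble(tg_signal = c(0, 1, 2.1), chr_signal = 1)
#' genotype_from_band_ratio(bands, het_calibration_ratio = 1)
#' @export
genotype_from_band_ratio <- function(bands, het_calibration_ratio) {
  assert_df_cols(bands, c("tg_signal", "chr_signal"))
  if (het_calibration_ratio <= 0) abort("calibration ratio must be positive")
  if (any(bands$tg_signal < 0) || any(bands$chr_signal < 0)) {
    abort("band densities must be non-negative")
  }
  if (any(bands$chr_signal == 0)) abort("`chr_signal` must be positive")
  bands %>%
    mutate(
      ratio = .data$tg_signal / .data$chr_signal,
      allele_count = as.integer(
        round_half_up(.data$ratio / het_calibration_ratio)
      ),
      genotype = dplyr::case_when(
        .data$allele_count == 0L ~ "wild-type",
        .data$allele_count == 1L ~ "het",
        .data$allele_count == 2L ~ "hom",
        TRUE ~ NA_character_
      )
    )
}

#' Map a simulated insertion end to end
#'
#' Convenience wrapper running the full inference chain on a read
#' simulation: depth profile, duplication detection, chimeric-pair
#' collection, junction calling and copy/size estimation.
#'
#' @param sim A `read_sim` over an insertion genome.
#' @param host_contig Host chromosome name.
#' @param unit_lengths Named vector of transgene contig lengths.
#' @param window Depth window, bases.
#' @param ... Passed on to [detect_duplication()].
#' @return An `insertion_report`.
#' @export
map_insertion <- function(sim, host_contig, unit_lengths, window = 1000,
                          ...) {
  stopifnot(inherits(sim, "read_sim"))
  prof <- compute_depth(sim, window = window, baseline_contig = host_contig)
  dup <- detect_duplication(prof, ...)
  dup1 <- if (nrow(dup) > 0) dup[which.max(dup$length), ] else NULL
  pairs <- collect_chimeric_pairs(sim, host_contig, names(unit_lengths))
  jx <- call_junctions(
    pairs, dup = dup1,
    insert_mean = sim$params$insert_mean, insert_sd = sim$params$insert_sd,
    read_len = sim$params$read_len
  )
  estimate_copies_and_size(
    prof, zygosity = if (!is.null(dup1)) dup1$zygosity else NULL,
    unit_lengths = unit_lengths, dup = dup1, junctions = jx,
    read_len = sim$params$read_len
  )
}
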
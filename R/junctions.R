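#' Collect host-transgene chimeric read pairs
#'
#' Extracts the discordant pairs with one mate mapped to the host chromosome
#' and the other to a transgene contig — the pair-level evidence of
#' insertion junctions. Each pair is reported once, from the host-side mate.
#' Concordant (proper) pairs and pairs involving only one contig class are
#' excluded.
#'
#' @param alignments Alignment tibble or `read_sim`.
#' @param host_contig Host chromosome name.
#' @param transgene_contigs Character vector of transgene contig names.
#' @return A tibble with columns `read_id`, `host_pos`, `host_strand`,
#'   `tg_contig`, `tg_pos`.
#' @export
collect_chimeric_pairs <- function(alignments, host_contig,
                                   transgene_contigs) {
  if (inherits(alignments, "read_sim")) alignments <- alignments$alignments
  assert_df_cols(alignments, c("contig", "pos", "strand", "mate_contig",
                               "mate_pos", "mapped", "mate_mapped", "proper"))
  alignments %>%
    filter(
      .data$mapped, .data$mate_mapped, !.data$proper,
      .data$contig == host_contig,
      .data$mate_contig %in% transgene_contigs
    ) %>%
    select(
      "read_id", host_pos = "pos", host_strand = "strand",
      tg_contig = "mate_contig", tg_pos = "mate_pos"
    )
}

#' Call insertion junctions from chimeric pairs
#'
#' Clusters the host-side mates of chimeric pairs by orientation:
#' forward-strand host reads face the insertion from its left and estimate
#' the downstream (right) host breakpoint; reverse-strand reads face it from
#' the right and estimate the upstream (left) breakpoint. The breakpoint
#' estimate extends the innermost host coordinate of each cluster by half
#' the mean inner gap of a fragment, `(insert_mean - 2 * read_len) / 2`,
#' the simplest unbiased choice under uniform fragment sampling; the
#' reported uncertainty is `2 * insert_sd`.
#'
#' When a duplication call is supplied, the two breakpoints are checked to
#' bracket (or abut, within one insert length) the duplicated interval — in
#' a target-site duplication the transgene array sits between the two copies
#' of the duplicated segment.
#'
#' @param pairs Chimeric pair tibble from [collect_chimeric_pairs()].
#' @param dup Optional one-row duplication call ([detect_duplication()]).
#' @param insert_mean,insert_sd Fragment length distribution used in
#'   sequencing, bases.
#' @param read_len Read length, bases.
#' @param min_support Minimum pairs per side (default 5).
#' @return A two-row tibble with columns `side` (`"left"`/`"right"`),
#'   `breakpoint`, `uncertainty`, `support`, `unit` (the adjoining transgene
#'   contig, the modal mate contig of the cluster).
#' @export
call_junctions <- function(pairs, dup = NULL, insert_mean = 400,
                           insert_sd = 35, read_len = 100, min_support = 5) {
  assert_df_cols(pairs, c("host_pos", "host_strand", "tg_contig"))
  offset <- (insert_mean - 2 * read_len) / 2
  fwd <- pairs %>% filter(.data$host_strand == "+")
  rev <- pairs %>% filter(.data$host_strand == "-")
  if (nrow(fwd) < min_support || nrow(rev) < min_support) {
    abort(sprintf(
      "insufficient junction evidence: %d forward / %d reverse pairs (need >= %d each)",
      nrow(fwd), nrow(rev), min_support
    ))
  }
  modal_unit <- function(x) names(sort(table(x), decreasing = TRUE))[1]
  out <- tibble(
    side = c("left", "right"),
    breakpoint = c(
      min(rev$host_pos) - offset,
      max(fwd$host_pos) + read_len - 1 + offset
    ),
    uncertainty = 2 * insert_sd,
    support = c(nrow(rev), nrow(fwd)),
    unit = c(modal_unit(rev$tg_contig), modal_unit(fwd$tg_contig))
  )
  if (!is.null(dup) && nrow(dup) == 1) {
    ok <- out$breakpoint[1] >= dup$start - insert_mean &&
      out$breakpoint[2] <= dup$end + insert_mean
    if (!ok) {
      warn("junction breakpoints do not bracket the duplication interval")
    }
  }
  out
}
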
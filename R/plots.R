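# ggplot2 displays for the main result types

#' Plot a windowed depth profile
#'
#' Normalized read depth per window, one panel per contig; the host panel
#' makes a target-site duplication visible as a step to ~2x.
#'
#' @param object A `depth_profile`.
#' @param contigs Optional subset of contigs to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot depth_profile
#' @export
autoplot.depth_profile <- function(object, contigs = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(contigs)) df <- df %>% filter(.data$contig %in% contigs)
  ggplot2::ggplot(df, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                   y = .data$depth_norm)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~contig, scales = "free_x") +
    ggplot2::labs(x = "position (bp)", y = "normalized depth") +
    ggplot2::theme_minimal()
}

#' Plot ganglionic fractions by sex with the critical region
#'
#' Scatter of per-animal ganglionic fractions split by sex and coloured by
#' megacolon status, with dashed lines at the critical-region bounds
#' (longest affected, shortest non-affected).
#'
#' @param cohort A cohort data frame (`sex`, `ganglionic_fraction`,
#'   `megacolon`).
#' @return A ggplot object.
#' @export
plot_ganglionic_zone <- function(cohort) {
  assert_df_cols(cohort, c("sex", "ganglionic_fraction", "megacolon"))
  cr <- tryCatch(critical_region(cohort), error = function(e) NULL)
  p <- ggplot2::ggplot(cohort, ggplot2::aes(
    x = .data$sex, y = .data$ganglionic_fraction, colour = .data$megacolon
  )) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = NULL, y = "ganglionic zone (% of colon length)",
                  colour = "megacolon") +
    ggplot2::theme_minimal()
  if (!is.null(cr)) {
    p <- p + ggplot2::geom_hline(yintercept = c(cr$lower, cr$upper),
                                 linetype = "dashed", colour = "grey50")
  }
  p
}

#' Plot migration tracks
#'
#' @param tracks A track table (`cell`, `t`, `x`, `y`).
#' @return A ggplot object.
#' @export
plot_tracks <- function(tracks) {
  assert_df_cols(tracks, c("cell", "t", "x", "y"))
  ggplot2::ggplot(tracks, ggplot2::aes(.data$x, .data$y,
                                       group = .data$cell,
                                       colour = .data$cell)) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' MA-style plot of a differential-expression result
#'
#' Log mean expression against display fold change, highlighting genes
#' passing the consensus rule at the given thresholds.
#'
#' @param object A `gutcrest_de` result.
#' @param min_fold,alpha Consensus thresholds used for highlighting.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gutcrest_de
#' @export
autoplot.gutcrest_de <- function(object, min_fold = 2, alpha = 0.001, ...) {
  df <- tidy(object) %>%
    filter(!.data$excluded) %>%
    mutate(
      consensus = abs(.data$fold_display) >= min_fold &
        .data$padj_exact < alpha & .data$padj_lrt < alpha,
      mean_expr = (.data$mean_control + .data$mean_mutant) / 2
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$mean_expr, .data$fold_display,
                                   colour = .data$consensus)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "mean normalized expression",
                  y = "fold change (signed display)",
                  colour = "consensus DE") +
    ggplot2::theme_minimal()
}
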
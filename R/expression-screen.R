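#' Consensus differential-expression filter
#'
#' Applies the screen's consensus rule: a gene is called differentially
#' expressed when its display fold change is at least `min_fold` in
#' magnitude **and** both testing schemes give a Benjamini-Hochberg
#' adjusted p-value below `alpha` (default 0.001). Tallies of up- and
#' downregulated calls are reported alongside the filtered set.
#'
#' @param records A `gutcrest_de` result or any data frame with columns
#'   `fold_display`, `padj_exact`, `padj_lrt`.
#' @param min_fold Minimum display fold magnitude (2 for the genome-wide
#'   screen, 4 for the most-deregulated list).
#' @param alpha Adjusted-p threshold (default 0.001).
#' @return An object of class `gutcrest_consensus`: list with `genes` (the
#'   passing rows), `n_up`, `n_down`, `n_total`. `tidy()` returns the
#'   passing rows, `glance()` the tallies.
#' @examples
#' tab1 <- gutcrest_fixtures()$table1
#' glance(consensus_filter(tab1, min_fold = 4))
#' @export
consensus_filter <- function(records, min_fold = 2, alpha = 0.001) {
  assert_df_cols(records, c("fold_display", "padj_exact", "padj_lrt"))
  keep <- records %>%
    filter(
      abs(.data$fold_display) >= min_fold,
      .data$padj_exact < alpha,
      .data$padj_lrt < alpha
    )
  structure(
    list(
      genes = as_tibble(keep),
      n_up = sum(keep$fold_display > 0),
      n_down = sum(keep$fold_display < 0),
      n_total = nrow(keep),
      min_fold = min_fold, alpha = alpha
    ),
    class = "gutcrest_consensus"
  )
}

#' @export
print.gutcrest_consensus <- function(x, ...) {
  cat(sprintf(
    "<consensus DE set> %d genes at >= %g-fold, adj p < %g (%d up, %d down)\n",
    x$n_total, x$min_fold, x$alpha, x$n_up, x$n_down
  ))
  invisible(x)
}

#' @rdname consensus_filter
#' @param x A `gutcrest_consensus`.
#' @param ... Unused.
#' @method tidy gutcrest_consensus
#' @export
tidy.gutcrest_consensus <- function(x, ...) x$genes

#' @rdname consensus_filter
#' @method glance gutcrest_consensus
#' @export
glance.gutcrest_consensus <- function(x, ...) {
  tibble(
    n_up = x$n_up, n_down = x$n_down, n_total = x$n_total,
    min_fold = x$min_fold, alpha = x$alpha
  )
}

#' Sex-chromosome screen
#'
#' Partitions a differential-expression set into the two patterns that
#' could explain a male-biased phenotype: genes downregulated on chromosome
#' X (a deficiency expressed from a single allele in males, or female
#' protection via inactivation escape) and genes upregulated on chromosome
#' Y (male-specific overexpression). Both lists are sorted by position.
#'
#' @param de A data frame with columns `gene`, `chromosome`, `start`,
#'   `fold_display` (a `gutcrest_consensus` is accepted).
#' @param x_chrom,y_chrom Chromosome labels (defaults `"X"`, `"Y"`).
#' @return A list with tibbles `x_down` and `y_up`.
#' @examples
#' sex_linked_screen(gutcrest_fixtures()$table3)
#' @export
sex_linked_screen <- function(de, x_chrom = "X", y_chrom = "Y") {
  if (inherits(de, "gutcrest_consensus")) de <- de$genes
  assert_df_cols(de, c("gene", "chromosome", "start", "fold_display"))
  list(
    x_down = de %>%
      filter(.data$chromosome == x_chrom, .data$fold_display < 0) %>%
      arrange(.data$start),
    y_up = de %>%
      filter(.data$chromosome == y_chrom, .data$fold_display > 0) %>%
      arrange(.data$start)
  )
}

#' Rank insertion-proximal candidate genes
#'
#' Ranks upregulated genes on the insertion chromosome by genomic distance
#' to the insertion (repressive-element) position — the prioritization
#' criterion for a causative gene whose long-range repression was disrupted.
#' Intra-chromosomal regulatory contacts dominate, so only the insertion
#' chromosome is considered; only upregulation (relief of repression) is a
#' candidate signature, so downregulated genes are never ranked.
#'
#' @param de A data frame with columns `gene`, `chromosome`, `start`, `end`,
#'   `fold_display`.
#' @param insertion_position Position of the insertion on `chromosome`,
#'   bases.
#' @param chromosome Insertion chromosome label (default `"10"`).
#' @param min_fold Minimum display fold (default 4).
#' @return A tibble of candidates sorted by ascending `distance` (bases,
#'   minimum of the distances to the gene's start and end; 0 if the
#'   insertion lies inside the gene).
#' @examples
#' rank_insertion_candidates(gutcrest_fixtures()$table4,
#'                           insertion_position = 47985420)
#' @export
rank_insertion_candidates <- function(de, insertion_position,
                                      chromosome = "10", min_fold = 4) {
  if (inherits(de, "gutcrest_consensus")) de <- de$genes
  assert_df_cols(de, c("gene", "chromosome", "start", "end", "fold_display"))
  de %>%
    filter(.data$chromosome == !!chromosome,
           .data$fold_display >= min_fold) %>%
    mutate(
      distance = ifelse(
        insertion_position >= .data$start & insertion_position <= .data$end,
        0,
        pmin(abs(.data$start - insertion_position),
             abs(.data$end - insertion_position))
      )
    ) %>%
    arrange(.data$distance)
}

#' Hypergeometric term enrichment
#'
#' Two-sided enrichment/depletion test of a gene set against annotation
#' terms: for each term, the overlap between the set and the term's genes
#' is referred to the hypergeometric distribution over the universe, taking
#' twice the smaller tail (capped at 1); Benjamini-Hochberg adjustment is
#' applied across terms. A term is selected when its fold
#' enrichment is at least `min_fold` (or at most `1 / min_fold`) and its
#' adjusted p-value is below `alpha`.
#'
#' @param genes Character vector, the gene set (must be a subset of
#'   `universe`).
#' @param universe Character vector of all genes considered.
#' @param term_map A data frame with columns `gene`, `term` mapping universe
#'   genes to annotation terms.
#' @param alpha Adjusted-p threshold (default 0.01).
#' @param min_fold Fold enrichment/depletion threshold (default 2).
#' @return A tibble with one row per term: `term`, `hits`, `set_size`,
#'   `term_size`, `universe_size`, `fold_enrichment`, `p`, `padj`,
#'   `direction`, `selected`.
#' @export
hypergeom_enrichment <- function(genes, universe, term_map, alpha = 0.01,
                                 min_fold = 2) {
  if (length(genes) == 0) abort("empty gene set")
  genes <- unique(genes)
  universe <- unique(universe)
  if (!all(genes %in% universe)) {
    abort("`genes` must be a subset of `universe`")
  }
  assert_df_cols(term_map, c("gene", "term"))
  term_map <- term_map %>% filter(.data$gene %in% universe) %>% dplyr::distinct()
  n_set <- length(genes)
  n_uni <- length(universe)

  out <- term_map %>%
    group_by(.data$term) %>%
    summarise(
      hits = sum(unique(.data$gene) %in% genes),
      term_size = dplyr::n_distinct(.data$gene),
      .groups = "drop"
    ) %>%
    mutate(
      set_size = n_set,
      universe_size = n_uni,
      fold_enrichment = (.data$hits / n_set) / (.data$term_size / n_uni),
      p_enrich = phyper(.data$hits - 1, .data$term_size,
                        n_uni - .data$term_size, n_set, lower.tail = FALSE),
      p_deplete = phyper(.data$hits, .data$term_size,
                         n_uni - .data$term_size, n_set),
      p = pmin(1, 2 * pmin(.data$p_enrich, .data$p_deplete)),
      direction = ifelse(.data$fold_enrichment >= 1, "enriched", "depleted")
    ) %>%
    mutate(padj = p.adjust(.data$p, "BH")) %>%
    mutate(
      selected = (.data$fold_enrichment >= min_fold |
                    .data$fold_enrichment <= 1 / min_fold) &
        .data$padj < alpha
    ) %>%
    select("term", "hits", "set_size", "term_size", "universe_size",
           "fold_enrichment", "p", "padj", "direction", "selected") %>%
    arrange(.data$padj)
  out
}
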
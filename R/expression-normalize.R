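#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with
#' nonzero counts in every sample, of the ratio of the sample's count to the
#' gene's geometric mean across samples. Factors are rescaled by their
#' median so the typical sample has factor 1; a sample with twice the
#' sequencing depth of otherwise identical samples then gets factor 2
#' exactly. Factors are invariant to a global rescaling of all counts.
#'
#' @param counts A genes x samples matrix (or data frame of counts).
#' @return A tibble with columns `sample`, `size_factor`.
#' @examples
#' m <- cbind(a = c(10, 20), b = c(10, 20), c = c(20, 40))
#' median_ratio_normalize(m)
#' @export
median_ratio_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  keep <- rowSums(counts == 0) == 0
  if (!any(keep)) {
    abort("no gene has nonzero counts in all samples; cannot normalize")
  }
  m <- counts[keep, , drop = FALSE]
  log_geo <- rowMeans(log(m))
  raw <- apply(m, 2, function(col) median(exp(log(col) - log_geo)))
  tibble(
    sample = colnames(counts),
    size_factor = unname(raw / median(raw))
  )
}
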
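#' Simulate a negative-binomial RNA-seq count matrix
#'
#' Generates per-gene counts for a two-group design (default 2 mutant vs 2
#' control replicates, the usable-library design of the expression screen)
#' under a negative-binomial model with mean `mu` and variance
#' `mu + dispersion * mu^2`; `dispersion = 0` gives the Poisson limit.
#' Baseline expression is log-normal across genes; designated genes receive
#' a true fold change (ratio mutant / control, > 0; downregulation is
#' expressed as a ratio below 1, never as a negative number). Genes are
#' annotated with chromosome, start and end so the sex-chromosome and
#' insertion-proximity screens can run on simulated data.
#'
#' @param n_genes Number of genes.
#' @param n_reps_per_group Replicates per group.
#' @param lib_sizes Relative library sizes, length `2 * n_reps_per_group`
#'   (control samples first); default all 1.
#' @param dispersion NB dispersion (>= 0).
#' @param de_spec Named numeric vector: gene name -> true fold ratio (> 0).
#'   Gene names not matching the simulated gene ids (`gene00001`...) are an
#'   error. `NULL` for a null simulation.
#' @param mean_log_mu,sd_log_mu Log-normal baseline expression parameters
#'   (natural log of the per-gene mean).
#' @param chromosomes Chromosome labels to assign (uniformly); defaults
#'   include autosomes 1-19 plus X and Y.
#' @param seed Integer seed or `NULL`.
#' @return An object of class `count_sim`: list with `counts`
#'   (genes x samples integer matrix), `samples` (tibble: `sample`, `group`),
#'   `genes` (tibble: `gene`, `chromosome`, `start`, `end`, `base_mean`,
#'   `true_fold`).
#' @examples
#' cs <- simulate_counts(50, dispersion = 0.05, seed = 1)
#' dim(cs$counts)
#' @export
simulate_counts <- function(n_genes, n_reps_per_group = 2, lib_sizes = NULL,
                            dispersion = 0.05, de_spec = NULL,
                            mean_log_mu = log(100), sd_log_mu = 1,
                            chromosomes = c(as.character(1:19), "X", "Y"),
                            seed = NULL) {
  if (dispersion < 0) abort("`dispersion` must be >= 0")
  n_samples <- 2 * n_reps_per_group
  lib_sizes <- lib_sizes %||% rep(1, n_samples)
  if (any(lib_sizes <= 0)) abort("`lib_sizes` must be positive")
  if (length(lib_sizes) != n_samples) {
    abort("`lib_sizes` must have one entry per sample")
  }
  local_seed(seed)

  genes <- tibble(
    gene = sprintf("gene%05d", seq_len(n_genes)),
    chromosome = sample(chromosomes, n_genes, replace = TRUE),
    start = sample.int(150e6, n_genes),
    base_mean = exp(rnorm(n_genes, mean_log_mu, sd_log_mu)),
    true_fold = 1
  ) %>%
    mutate(end = .data$start + sample.int(1e5, n_genes)) %>%
    select("gene", "chromosome", "start", "end", "base_mean", "true_fold")

  if (!is.null(de_spec)) {
    if (is.null(names(de_spec))) abort("`de_spec` must be a named vector")
    if (any(de_spec <= 0)) {
      abort("true folds must be positive ratios; use reciprocals for downregulation")
    }
    hit <- match(names(de_spec), genes$gene)
    if (anyNA(hit)) abort("`de_spec` names must match simulated gene ids")
    genes$true_fold[hit] <- unname(de_spec)
  }

  samples <- tibble(
    sample = c(
      sprintf("control_%d", seq_len(n_reps_per_group)),
      sprintf("mutant_%d", seq_len(n_reps_per_group))
    ),
    group = rep(c("control", "mutant"), each = n_reps_per_group),
    lib_size = lib_sizes
  )

  mu <- outer(genes$base_mean, lib_sizes) *
    cbind(matrix(1, n_genes, n_reps_per_group),
          matrix(genes$true_fold, n_genes, n_reps_per_group))
  counts <- if (dispersion == 0) {
    matrix(rpois(length(mu), mu), n_genes, n_samples)
  } else {
    matrix(rnbinom(length(mu), size = 1 / dispersion, mu = mu),
           n_genes, n_samples)
  }
  dimnames(counts) <- list(genes$gene, samples$sample)

  structure(
    list(counts = counts, samples = samples, genes = genes),
    class = "count_sim"
  )
}

#' @export
print.count_sim <- function(x, ...) {
  cat(sprintf(
    "<count_sim> %d genes x %d samples, %d true DE gene(s)\n",
    nrow(x$counts), ncol(x$counts), sum(x$genes$true_fold != 1)
  ))
  invisible(x)
}
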
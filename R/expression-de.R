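#' Negative-binomial differential expression test (dual scheme)
#'
#' Tests each gene for a mutant-vs-control expression difference under a
#' negative-binomial model (variance `mu + phi * mu^2`), producing two
#' p-values per gene from two independent testing schemes whose agreement
#' the consensus rule ([consensus_filter()]) later requires:
#'
#' * **exact** — a conditional NB exact test: per-gene moment dispersion is
#'   moderated toward the common dispersion, group sums of normalized
#'   (pseudo-)counts are compared conditionally on their total, and the
#'   p-value sums the probabilities of all outcomes at most as likely as
#'   the observed split;
#' * **lrt** — a likelihood-ratio test of group means with per-gene moment
#'   dispersion shrunk toward a fitted mean-dispersion trend, referred to a
#'   chi-squared distribution with one degree of freedom.
#'
#' Both schemes receive Benjamini-Hochberg adjustment across tested genes.
#' Genes with zero counts in every sample are excluded from testing and
#' flagged. Fold change is the ratio of normalized group means
#' (mutant / control); the signed display convention shows ratios below 1
#' as negative reciprocals.
#'
#' @param counts A genes x samples count matrix, or a `count_sim`.
#' @param groups Factor-like of length `ncol(counts)` with two levels;
#'   defaults to the `count_sim` design. The **first** level is the
#'   reference (control).
#' @param prior_df Moderation weight (prior degrees of freedom) pulling
#'   per-gene dispersions toward the common value in the exact scheme.
#' @param trend_weight Weight of the mean-dispersion trend in the shrunken
#'   per-gene dispersion of the LRT scheme.
#' @return An object of class `gutcrest_de`: a tibble with one row per gene
#'   (`gene`, `mean_control`, `mean_mutant`, `fold`, `fold_display`,
#'   `p_exact`, `p_lrt`, `padj_exact`, `padj_lrt`, `excluded`), with the
#'   size factors and dispersion summaries as attributes. `tidy()` returns
#'   the tibble, `glance()` a one-row summary.
#' @examples
#' cs <- simulate_counts(200, de_spec = c(gene00001 = 5), seed = 1)
#' de <- nb_de_test(cs)
#' head(tidy(de))
#' @export
nb_de_test <- function(counts, groups = NULL, prior_df = 10,
                       trend_weight = 0.5) {
  if (inherits(counts, "count_sim")) {
    groups <- groups %||% counts$samples$group
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("gene%05d", seq_len(nrow(counts)))
  }
  groups <- as.factor(groups)
  if (nlevels(groups) != 2) abort("`groups` must have exactly two levels")
  if (length(groups) != ncol(counts)) {
    abort("`groups` must have one entry per sample")
  }
  if (any(tabulate(groups) < 2)) abort("need >= 2 samples per group")
  ref <- levels(groups)[1]
  alt <- levels(groups)[2]

  excluded <- rowSums(counts) == 0
  sf <- median_ratio_normalize(counts)$size_factor
  z <- sweep(counts, 2, sf, "/") # normalized counts
  i1 <- which(groups == ref); i2 <- which(groups == alt)
  n1 <- length(i1); n2 <- length(i2)
  mu1 <- rowMeans(z[, i1, drop = FALSE])
  mu2 <- rowMeans(z[, i2, drop = FALSE])
  mu_all <- rowMeans(z)

  # method-of-moments dispersion, pooled within groups
  v_pool <- ((n1 - 1) * apply(z[, i1, drop = FALSE], 1, var) +
               (n2 - 1) * apply(z[, i2, drop = FALSE], 1, var)) /
    (n1 + n2 - 2)
  phi_mom <- pmax(0, (v_pool - mu_all) / mu_all^2)
  phi_mom[!is.finite(phi_mom)] <- 0

  tested <- which(!excluded)
  phi_common <- stats::weighted.mean(
    phi_mom[tested], w = pmin(mu_all[tested], 1000)
  )
  resid_df <- n1 + n2 - 2
  phi_exact <- (prior_df * phi_common + resid_df * phi_mom) /
    (prior_df + resid_df)

  # mean-dispersion trend on moderately expressed genes
  phi_trend <- rep(phi_common, nrow(counts))
  fit_idx <- tested[mu_all[tested] >= 5]
  if (length(fit_idx) >= 20) {
    lo <- lowess(log(mu_all[fit_idx]), phi_mom[fit_idx], f = 0.5)
    ux <- !duplicated(lo$x)
    phi_trend <- approx(lo$x[ux], lo$y[ux], xout = log(pmax(mu_all, 1e-8)),
                        rule = 2)$y
    phi_trend <- pmax(phi_trend, 0)
  }
  phi_lrt <- pmax(trend_weight * phi_trend + (1 - trend_weight) * phi_mom,
                  1e-8)

  p_exact <- rep(NA_real_, nrow(counts))
  p_lrt <- rep(NA_real_, nrow(counts))
  y1 <- round(rowSums(z[, i1, drop = FALSE]))
  y2 <- round(rowSums(z[, i2, drop = FALSE]))
  for (g in tested) {
    p_exact[g] <- nb_exact_p(y1[g], y2[g], n1, n2, max(phi_exact[g], 1e-8))
  }
  p_lrt[tested] <- nb_lrt_p(
    counts[tested, , drop = FALSE], sf, i1, i2, phi_lrt[tested]
  )

  out <- tibble(
    gene = rownames(counts),
    mean_control = mu1, mean_mutant = mu2,
    fold = mu2 / mu1,
    fold_display = display_fold(mu2 / mu1),
    p_exact = p_exact, p_lrt = p_lrt,
    padj_exact = NA_real_, padj_lrt = NA_real_,
    excluded = excluded
  )
  out$padj_exact[tested] <- p.adjust(p_exact[tested], "BH")
  out$padj_lrt[tested] <- p.adjust(p_lrt[tested], "BH")
  attr(out, "size_factors") <- sf
  attr(out, "phi_common") <- phi_common
  attr(out, "groups") <- c(control = ref, mutant = alt)
  class(out) <- c("gutcrest_de", class(out))
  out
}

# Conditional NB exact test on group sums. With equal per-sample means, the
# sum of n i.i.d. NB(mu, phi) counts is NB(n * mu, phi / n); conditioning on
# the total, the probability of every split y + (t - y) is evaluated and the
# p-value sums the masses <= that of the observed split (double tail by
# probability ordering).
nb_exact_p <- function(y1, y2, n1, n2, phi) {
  t_sum <- y1 + y2
  if (t_sum == 0) return(1)
  mu0 <- t_sum / (n1 + n2)
  m1 <- n1 * mu0; s1 <- n1 / phi
  m2 <- n2 * mu0; s2 <- n2 / phi
  # enumerate only where mass is non-negligible
  sd1 <- sqrt(m1 + phi / n1 * m1^2)
  lo <- max(0, floor(m1 - 60 * sd1))
  hi <- min(t_sum, ceiling(m1 + 60 * sd1))
  ys <- lo:hi
  logp <- dnbinom(ys, size = s1, mu = m1, log = TRUE) +
    dnbinom(t_sum - ys, size = s2, mu = m2, log = TRUE)
  logp <- logp - max(logp)
  p <- exp(logp)
  p <- p / sum(p)
  obs <- which(ys == y1)
  if (length(obs) == 0) return(0) # observed split far outside the bulk
  min(1, sum(p[p <= p[obs] * (1 + 1e-10)]))
}

# Vectorized NB likelihood-ratio test: group means estimated as
# sum(counts) / sum(size factors) (quasi-MLE with size-factor offsets).
nb_lrt_p <- function(counts, sf, i1, i2, phi) {
  mu1 <- rowSums(counts[, i1, drop = FALSE]) / sum(sf[i1])
  mu2 <- rowSums(counts[, i2, drop = FALSE]) / sum(sf[i2])
  mu0 <- rowSums(counts) / sum(sf)
  ll <- function(mu_vec, cols) {
    out <- 0
    for (j in cols) {
      out <- out + dnbinom(counts[, j], size = 1 / phi,
                           mu = pmax(mu_vec * sf[j], 1e-10), log = TRUE)
    }
    out
  }
  ll_alt <- ll(mu1, i1) + ll(mu2, i2)
  ll_null <- ll(mu0, c(i1, i2))
  stat <- pmax(2 * (ll_alt - ll_null), 0)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

#' @rdname nb_de_test
#' @param x A `gutcrest_de` object.
#' @param ... Unused.
#' @method tidy gutcrest_de
#' @export
tidy.gutcrest_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "gutcrest_de")
  as_tibble(out)
}

#' @rdname nb_de_test
#' @method glance gutcrest_de
#' @export
glance.gutcrest_de <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_tested = sum(!x$excluded),
    n_excluded = sum(x$excluded),
    phi_common = attr(x, "phi_common")
  )
}
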
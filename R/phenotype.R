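#' Critical region for developing megacolon
#'
#' The critical region is the interval of ganglionic fraction bracketing the
#' obstruction threshold: its lower bound is the shortest ganglionic zone
#' observed in a non-affected animal and its upper bound the longest
#' ganglionic zone found in a megacolon case. When the two groups overlap
#' (`upper >= lower`), the threshold must lie between them.
#'
#' @param cohort A data frame with columns `ganglionic_fraction` (percent of
#'   colon length) and `megacolon` (logical).
#' @return A one-row tibble with columns `lower`, `upper`, `overlap`.
#' @examples
#' cohort <- gutcrest_fixtures()$fig1e
#' critical_region(cohort)
#' @export
critical_region <- function(cohort) {
  assert_df_cols(cohort, c("ganglionic_fraction", "megacolon"))
  affected <- cohort$ganglionic_fraction[cohort$megacolon]
  unaffected <- cohort$ganglionic_fraction[!cohort$megacolon]
  if (length(affected) == 0) {
    abort("one-sided region: no megacolon-affected animals in the cohort")
  }
  if (length(unaffected) == 0) {
    abort("one-sided region: no non-affected animals in the cohort")
  }
  lower <- min(unaffected)
  upper <- max(affected)
  tibble(lower = lower, upper = upper, overlap = upper >= lower)
}

#' Megacolon penetrance by sex
#'
#' Tabulates megacolon incidence per sex and the male:female ratio among
#' affected animals. The ratio is `NA` (reported as undefined) when no
#' female is affected.
#'
#' @param cohort A data frame with columns `sex` (`"M"`/`"F"`) and
#'   `megacolon` (logical).
#' @return A tibble with one row per sex (`sex`, `n`, `n_affected`,
#'   `penetrance`) carrying the attribute `"sex_ratio"` (male:female among
#'   affected).
#' @export
penetrance_by_sex <- function(cohort) {
  assert_df_cols(cohort, c("sex", "megacolon"))
  if (nrow(cohort) == 0) abort("empty cohort")
  out <- cohort %>%
    group_by(.data$sex) %>%
    summarise(
      n = dplyr::n(), n_affected = sum(.data$megacolon),
      penetrance = mean(.data$megacolon), .groups = "drop"
    )
  aff <- setNames(out$n_affected, out$sex)
  m <- unname(aff["M"] %||% 0); f <- unname(aff["F"] %||% 0)
  m <- ifelse(is.na(m), 0, m); f <- ifelse(is.na(f), 0, f)
  attr(out, "sex_ratio") <- if (f == 0) NA_real_ else m / f
  out
}

#' Mean ganglionic fraction by sex
#'
#' @param cohort A data frame with columns `sex` and `ganglionic_fraction`.
#' @return A tibble with one row per sex: `sex`, `n`, `mean`, `sd`.
#' @export
mean_ganglionic_by_sex <- function(cohort) {
  assert_df_cols(cohort, c("sex", "ganglionic_fraction"))
  if (nrow(cohort) == 0) abort("empty cohort")
  cohort %>%
    group_by(.data$sex) %>%
    summarise(
      n = dplyr::n(),
      mean = mean(.data$ganglionic_fraction),
      sd = sd(.data$ganglionic_fraction),
      .groups = "drop"
    )
}

#' Predicted penetrance under the tipping-point model
#'
#' Under the threshold model, an animal develops megacolon when its
#' ganglionic fraction falls below the tipping point, so the penetrance of a
#' sex whose fractions are Gaussian `(mu, sigma)` is the lower-tail
#' probability `Phi((threshold - mu) / sigma)`. A sex whose mean sits at the
#' threshold has penetrance 1/2 — the situation of males in this model,
#' while females sit just beyond the tipping point. `sigma = 0` gives the
#' deterministic step function.
#'
#' @param mu Mean ganglionic fraction, percent.
#' @param sigma Standard deviation, percentage points (>= 0).
#' @param threshold Tipping point, percent.
#' @return Penetrance probability in `[0, 1]` (vectorized over `mu`).
#' @examples
#' predict_penetrance(mu = 79, sigma = 5, threshold = 80)
#' @export
predict_penetrance <- function(mu, sigma, threshold = 80) {
  if (any(sigma < 0)) abort("`sigma` must be >= 0")
  ifelse(
    sigma == 0,
    ifelse(mu < threshold, 1, ifelse(mu > threshold, 0, 0.5)),
    pnorm((threshold - mu) / sigma)
  )
}

#' Welch two-sample t-test
#'
#' Two-sided comparison of two groups with the unequal-variance (Welch)
#' form of the t statistic and Satterthwaite degrees of freedom — a robust
#' superset of the Student's t-test used for the study's quantifications.
#' When both groups are constant with equal means, `p = 1` by convention;
#' constant groups with different means give `p = 0`.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @return A one-row tibble: `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @examples
#' welch_t(rnorm(10), rnorm(10, 1))
#' @export
welch_t <- function(group_a, group_b) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    abort("each group needs at least two observations")
  }
  if (var(group_a) == 0 && var(group_b) == 0) {
    same <- isTRUE(all.equal(mean(group_a), mean(group_b)))
    return(tibble(
      t = if (same) 0 else sign(mean(group_a) - mean(group_b)) * Inf,
      df = length(group_a) + length(group_b) - 2,
      p = if (same) 1 else 0,
      mean_a = mean(group_a), mean_b = mean(group_b)
    ))
  }
  ht <- t.test(group_a, group_b, var.equal = FALSE)
  tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, mean_a = mean(group_a), mean_b = mean(group_b)
  )
}
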
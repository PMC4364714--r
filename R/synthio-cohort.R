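#' Simulate a cohort of homozygous animals with threshold-determined megacolon
#'
#' Draws per-animal ganglionic fractions (percentage of colon length covered
#' by myenteric ganglia, measured from the cecum) from sex-specific Gaussians
#' truncated to `[0, 100]`, and calls megacolon deterministically below the
#' obstruction threshold: in this model intestinal blockage occurs
#' systematically once ganglionosis falls short of the tipping point
#' (default 80% of colon length).
#'
#' Default means are the study conditions for homozygous animals: weaning age
#' 79% (male) / 89% (female); neonates 74% / 90%. The spread is not reported
#' per animal, so a common standard deviation of 5 percentage points is used.
#'
#' @param n_male,n_female Number of animals per sex (>= 0).
#' @param mu_male,mu_female Mean ganglionic fraction per sex (percent). If
#'   `NULL`, age-group defaults are used.
#' @param sigma Standard deviation (percentage points, >= 0).
#' @param threshold Megacolon threshold in (0, 100); fractions strictly below
#'   it are called affected.
#' @param age_group `"weaning"` or `"neonate"`.
#' @param seed Integer seed or `NULL`.
#' @return A tibble with columns `id`, `sex` (`"M"`/`"F"`), `age_group`,
#'   `ganglionic_fraction`, `megacolon`.
#' @examples
#' simulate_cohort(5, 5, seed = 1)
#' @export
simulate_cohort <- function(n_male, n_female, mu_male = NULL, mu_female = NULL,
                            sigma = 5, threshold = 80,
                            age_group = c("weaning", "neonate"), seed = NULL) {
  if (n_male < 0 || n_female < 0) abort("animal counts must be non-negative")
  if (sigma < 0) abort("`sigma` must be >= 0")
  if (threshold <= 0 || threshold >= 100) abort("`threshold` must be in (0, 100)")
  age_group <- match.arg(age_group)
  defaults <- list(
    weaning = c(male = 79, female = 89),
    neonate = c(male = 74, female = 90)
  )[[age_group]]
  mu_male <- mu_male %||% defaults[["male"]]
  mu_female <- mu_female %||% defaults[["female"]]
  local_seed(seed)

  draw <- function(n, mu) {
    x <- rnorm(n, mu, sigma)
    bad <- which(x < 0 | x > 100) # truncate by redraw
    while (length(bad) > 0) {
      x[bad] <- rnorm(length(bad), mu, sigma)
      bad <- bad[x[bad] < 0 | x[bad] > 100]
    }
    x
  }
  frac <- c(draw(n_male, mu_male), draw(n_female, mu_female))
  n <- n_male + n_female
  tibble(
    id = sprintf("A%04d", seq_len(n)),
    sex = rep(c("M", "F"), c(n_male, n_female)),
    age_group = age_group,
    ganglionic_fraction = frac,
    megacolon = frac < threshold
  )
}
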
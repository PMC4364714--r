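# circular helpers ----------------------------------------------------------

circ_mean <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))
circ_R <- function(theta) sqrt(mean(sin(theta))^2 + mean(cos(theta))^2)

# inverse of A1(kappa) = I1(kappa)/I0(kappa): standard piecewise
# approximation used to estimate a von Mises concentration from the mean
# resultant length
a1inv <- function(r) {
  if (r >= 1) return(Inf)
  if (r < 0.53) {
    2 * r + r^3 + 5 * r^5 / 6
  } else if (r < 0.85) {
    -0.4 + 1.39 * r + 0.43 / (1 - r)
  } else {
    1 / (r^3 - 4 * r^2 + 3 * r)
  }
}

# metrics -------------------------------------------------------------------

#' Mean migration speed of one track
#'
#' Total path length divided by total elapsed time: the sum of successive
#' step displacements over the time from first to last fix.
#'
#' @param track A data frame with columns `t` (minutes, strictly increasing)
#'   and `x`, `y` (micrometres), one cell.
#' @return Speed in um/min.
#' @examples
#' track_speed(tibble::tibble(t = 0:3, x = 0:3, y = 0))
#' @export
track_speed <- function(track) {
  assert_df_cols(track, c("t", "x", "y"))
  if (nrow(track) < 2) abort("a track needs at least two time points")
  if (any(diff(track$t) <= 0)) abort("timestamps must be strictly increasing")
  steps <- sqrt(diff(track$x)^2 + diff(track$y)^2)
  sum(steps) / (track$t[nrow(track)] - track$t[1])
}

#' Directionality of one track
#'
#' Converts per-step headings to deviations from the reference axis (the
#' mesentery orientation) and summarizes them with circular statistics: the
#' circular mean deviation, the mean resultant length `R` (1 = all steps in
#' the same direction, 0 = no preferred direction), and the straightness
#' index (net displacement / path length). Zero-length steps carry no
#' heading and are skipped; a track of only zero-length steps has no
#' defined direction.
#'
#' @param track A data frame with columns `t`, `x`, `y` (one cell).
#' @param reference_angle Reference axis in radians; defaults to the track's
#'   `"reference_angle"` attribute, else 0.
#' @return A one-row tibble: `mean_deviation` (radians), `R`, `straightness`,
#'   `n_steps`.
#' @export
track_direction <- function(track, reference_angle = NULL) {
  assert_df_cols(track, c("t", "x", "y"))
  if (nrow(track) < 2) abort("a track needs at least two time points")
  reference_angle <- reference_angle %||%
    attr(track, "reference_angle") %||% 0
  dx <- diff(track$x); dy <- diff(track$y)
  nz <- dx != 0 | dy != 0
  if (!any(nz)) abort("all steps have zero length: direction undefined")
  dev <- wrap_angle(atan2(dy[nz], dx[nz]) - reference_angle)
  net <- sqrt((track$x[nrow(track)] - track$x[1])^2 +
                (track$y[nrow(track)] - track$y[1])^2)
  path <- sum(sqrt(dx^2 + dy^2))
  tibble(
    mean_deviation = circ_mean(dev),
    R = circ_R(dev),
    straightness = if (path > 0) net / path else NA_real_,
    n_steps = sum(nz)
  )
}

#' Per-cell track metrics
#'
#' Applies [track_speed()] and [track_direction()] to every cell of a track
#' table, adding the net (start-to-end) speed.
#'
#' @param tracks A data frame with columns `cell`, `t`, `x`, `y`.
#' @param reference_angle Reference axis in radians (default: attribute of
#'   `tracks`, else 0).
#' @return A tibble with one row per cell: `cell`, `mean_speed`,
#'   `net_speed`, `straightness`, `mean_deviation`, `R`, `n_steps`.
#' @examples
#' tr <- simulate_tracks(5, duration = 60, dt = 5, seed = 1)
#' track_metrics(tr)
#' @export
track_metrics <- function(tracks, reference_angle = NULL) {
  assert_df_cols(tracks, c("cell", "t", "x", "y"))
  reference_angle <- reference_angle %||%
    attr(tracks, "reference_angle") %||% 0
  tracks %>%
    group_by(.data$cell) %>%
    group_modify(function(d, key) {
      dir <- track_direction(d, reference_angle)
      elapsed <- d$t[nrow(d)] - d$t[1]
      net <- sqrt((d$x[nrow(d)] - d$x[1])^2 + (d$y[nrow(d)] - d$y[1])^2)
      tibble(
        mean_speed = track_speed(d),
        net_speed = net / elapsed,
        straightness = dir$straightness,
        mean_deviation = dir$mean_deviation,
        R = dir$R,
        n_steps = dir$n_steps
      )
    }) %>%
    ungroup()
}

# group test ----------------------------------------------------------------

#' Watson-Williams test for equal mean directions
#'
#' Circular one-way ANOVA comparing the mean directions of two or more
#' groups of angles, with the standard concentration correction
#' `1 + 3 / (8 * kappa_hat)`. Assumes von Mises-like samples with a common,
#' reasonably high concentration; a warning is issued when the pooled
#' within-group mean resultant length falls below 0.45, where the test is
#' unreliable.
#'
#' @param angles A data frame with columns `angle` (radians) and `group`, or
#'   a numeric vector of angles (then `group` must be given).
#' @param group Grouping vector when `angles` is a numeric vector.
#' @return An object of class `gutcrest_ww`; `tidy()`/`glance()` return a
#'   one-row tibble with `statistic` (F), `df1`, `df2`, `p`, `kappa`,
#'   `r_within`.
#' @examples
#' a <- rvonmises(20, 0, 5); b <- rvonmises(20, pi / 2, 5)
#' watson_williams(data.frame(angle = c(a, b),
#'                            group = rep(c("a", "b"), each = 20)))
#' @export
watson_williams <- function(angles, group = NULL) {
  if (is.data.frame(angles)) {
    assert_df_cols(angles, c("angle", "group"))
    group <- angles$group
    angles <- angles$angle
  }
  if (is.null(group)) abort("`group` must be supplied")
  group <- as.factor(group)
  if (nlevels(group) < 2) abort("need at least two groups")
  ns <- tabulate(group)
  if (any(ns < 2)) abort("each group needs at least two angles")

  n_tot <- length(angles)
  k <- nlevels(group)
  Rs <- vapply(levels(group), function(g) {
    th <- angles[group == g]
    R <- circ_R(th) * length(th)
    if (R < sqrt(.Machine$double.eps)) {
      abort(sprintf("group '%s' has an undefined mean direction", g))
    }
    R
  }, numeric(1))
  R_tot <- circ_R(angles) * n_tot
  r_w <- sum(Rs) / n_tot
  if (r_w < 0.45) {
    warn("within-group concentration is low (R < 0.45); the Watson-Williams test may be unreliable")
  }
  kappa <- a1inv(r_w)
  correction <- 1 + 3 / (8 * kappa)
  f_stat <- correction * ((n_tot - k) * (sum(Rs) - R_tot)) /
    ((k - 1) * (n_tot - sum(Rs)))
  f_stat <- max(f_stat, 0)
  structure(
    list(
      statistic = f_stat, df1 = k - 1, df2 = n_tot - k,
      p = pf(f_stat, k - 1, n_tot - k, lower.tail = FALSE),
      kappa = kappa, r_within = r_w, n = n_tot, k = k
    ),
    class = "gutcrest_ww"
  )
}

#' @export
print.gutcrest_ww <- function(x, ...) {
  cat(sprintf(
    "Watson-Williams test: F(%d, %d) = %.3f, p = %.4g (kappa = %.2f)\n",
    x$df1, x$df2, x$statistic, x$p, x$kappa
  ))
  invisible(x)
}

#' @rdname watson_williams
#' @param x A `gutcrest_ww` object.
#' @param ... Unused.
#' @method tidy gutcrest_ww
#' @export
tidy.gutcrest_ww <- function(x, ...) {
  tibble(
    statistic = x$statistic, df1 = x$df1, df2 = x$df2, p = x$p,
    kappa = x$kappa, r_within = x$r_within
  )
}

#' @rdname watson_williams
#' @method glance gutcrest_ww
#' @export
glance.gutcrest_ww <- function(x, ...) tidy(x)

# explants ------------------------------------------------------------------

#' Feret's diameter of a 2-D point set
#'
#' The maximum pairwise Euclidean distance (maximum caliper width), used as
#' the spread of cells that invaded a collagen gel. Computed directly for
#' small sets; for more than 500 points the convex hull is taken first,
#' since the diameter is attained between hull vertices.
#'
#' @param points A data frame with columns `x`, `y` (micrometres).
#' @return Diameter in the units of the coordinates.
#' @examples
#' feret_diameter(data.frame(x = c(0, 150), y = c(0, 0)))
#' @export
feret_diameter <- function(points) {
  assert_df_cols(points, c("x", "y"))
  if (nrow(points) < 2) abort("Feret's diameter needs at least two points")
  xy <- as.matrix(points[, c("x", "y")])
  if (nrow(xy) > 500) {
    xy <- xy[grDevices::chull(xy), , drop = FALSE]
  }
  max(dist(xy))
}

#' Explant invasion summary
#'
#' Summarizes one explant migration assay: the number of cells that invaded
#' the gel, their spread (Feret's diameter), and whether the spread exceeds
#' the explant-diameter threshold — 200 um, the average diameter of the
#' intestinal slices used in the assay — indicating active migration away
#' from the explant. The inequality is strict: a spread of exactly the
#' threshold is not called active.
#'
#' @param points A data frame with columns `x`, `y`, one row per invading
#'   cell (possibly empty).
#' @param threshold Active-migration threshold in um (default 200).
#' @return A one-row tibble: `n_cells`, `feret`, `active`.
#' @examples
#' explant_summary(data.frame(x = c(0, 250), y = c(0, 0)))
#' @export
explant_summary <- function(points, threshold = 200) {
  assert_df_cols(points, c("x", "y"))
  n <- nrow(points)
  feret <- if (n >= 2) feret_diameter(points) else 0
  tibble(n_cells = n, feret = feret, active = feret > threshold)
}
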
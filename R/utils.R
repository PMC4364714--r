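# Internal helpers shared across modules.

# Set the RNG state locally: callers pass `seed = NULL` to use the current
# stream, or an integer for full reproducibility. Restores the global state
# on exit so generators compose without clobbering each other.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  withr::defer(
    {
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
    },
    envir = envir
  )
  set.seed(as.integer(seed))
  invisible(NULL)
}

# round-half-up to integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

# wrap angles into (-pi, pi]
wrap_angle <- function(theta) {
  out <- (theta + pi) %% (2 * pi) - pi
  out[out <= -pi] <- pi
  out
}

assert_df_cols <- function(x, cols, arg = deparse(substitute(x))) {
  if (!is.data.frame(x)) {
    abort(sprintf("`%s` must be a data frame", arg))
  }
  missing <- setdiff(cols, names(x))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column(s): %s",
      arg, paste(missing, collapse = ", ")
    ))
  }
  invisible(x)
}

# Signed display convention for fold changes: ratios below 1 are shown as
# -1/ratio, matching the "(-13.3)"-style entries of expression tables.
#' Convert between ratio and signed display fold change
#'
#' Expression results store fold change internally as a positive ratio
#' (mutant / control). For display, ratios below 1 are shown as negative
#' reciprocals, e.g. a ratio of 0.25 displays as -4. `display_fold()` maps
#' ratio to display value, `ratio_fold()` inverts it.
#'
#' @param ratio Positive fold-change ratio(s).
#' @param display Signed display fold(s); magnitude always >= 1.
#' @return A numeric vector.
#' @examples
#' display_fold(c(4, 0.25))
#' ratio_fold(display_fold(0.2))
#' @export
display_fold <- function(ratio) {
  if (any(ratio < 0, na.rm = TRUE)) abort("fold ratios must be positive")
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' @rdname display_fold
#' @export
ratio_fold <- function(display) {
  ifelse(display >= 0, display, -1 / display)
}
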
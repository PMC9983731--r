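#' Theil-Sen trend estimate
#'
#' Robust nonparametric trend: the slope is the median of all pairwise slopes
#' `(value_j - value_i) / (year_j - year_i)` over `i < j`, and the intercept
#' is `median(value - slope * year)`. Even pair counts take the mean of the
#' central pair (the usual median convention).
#'
#' @param series An [annual_series()].
#' @param from,to Optional period restriction (inclusive years).
#' @return A `trend_estimate` list: `slope` (units yr-1), `intercept`,
#'   `period`, `n`, `n_pairs`, plus `likelihood`/`category` slots filled by
#'   [bootstrap_trend_likelihood()] / [classify_trend_likelihood()].
#' @examples
#' theil_sen(annual_series(0:2, c(0, 2, 1)))$slope  # 0.5
#' @export
theil_sen <- function(series, from = -Inf, to = Inf) {
  s <- series_window(series, from, to)
  keep <- !is.na(s$value)
  yr <- s$year[keep]
  v <- s$value[keep]
  n <- length(v)
  if (n < 3L) stop("Theil-Sen needs at least 3 non-missing points",
                   call. = FALSE)
  ij <- utils::combn(n, 2L)
  slopes <- (v[ij[2L, ]] - v[ij[1L, ]]) / (yr[ij[2L, ]] - yr[ij[1L, ]])
  slope <- stats::median(slopes)
  structure(
    list(slope = slope,
         intercept = stats::median(v - slope * yr),
         period = c(min(yr), max(yr)),
         n = n,
         n_pairs = ncol(ij),
         likelihood = NA_real_,
         category = NA_character_),
    class = "trend_estimate")
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf("<trend_estimate> %d-%d: slope %.4g per yr (n = %d, %d pairs)\n",
              x$period[1], x$period[2], x$slope, x$n, x$n_pairs))
  if (!is.na(x$likelihood)) {
    cat(sprintf("  trend likelihood %.3f: %s\n", x$likelihood, x$category))
  }
  invisible(x)
}

#' Loess-smoothed annual series
#'
#' Locally weighted polynomial smoothing evaluated at the observed years,
#' with tricube weights. Defaults are span 0.75 and local quadratics, the
#' common loess defaults.
#'
#' @param series An [annual_series()] with at least 10 non-missing points.
#' @param span Smoothing span in (0, 1].
#' @param degree Local polynomial degree, 1 or 2.
#' @return An [annual_series()] on the same year index.
#' @export
loess_smooth <- function(series, span = 0.75, degree = 2) {
  keep <- !is.na(series$value)
  if (sum(keep) < 10L) stop("loess smoothing needs at least 10 points",
                            call. = FALSE)
  if (span <= 0 || span > 1) stop("span must be in (0, 1]", call. = FALSE)
  if (span * sum(keep) < 3) {
    stop("span too small: local neighborhoods need at least 3 points",
         call. = FALSE)
  }
  fit <- stats::loess(value ~ year, data = series[keep, ],
                      span = span, degree = degree,
                      family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  sm <- stats::predict(fit, newdata = data.frame(year = series$year))
  annual_series(series$year, sm, units = series_units(series))
}

#' Percent change between two years of a series
#'
#' Signed percent change `100 * (value(y2) - value(y1)) / value(y1)`, the
#' summary used for decadal flux-change tables.
#'
#' @param series An [annual_series()].
#' @param y1,y2 Start and end year; both must be present and `value(y1) != 0`.
#' @return Percent (signed scalar).
#' @examples
#' percent_change(annual_series(c(1975, 1985), c(100, 118)), 1975, 1985) # +18
#' @export
percent_change <- function(series, y1, y2) {
  v1 <- series_value(series, y1)
  v2 <- series_value(series, y2)
  if (is.na(v1) || is.na(v2)) stop("missing value at an endpoint year",
                                   call. = FALSE)
  if (v1 == 0) stop("percent change undefined from a zero base year",
                    call. = FALSE)
  100 * (v2 - v1) / v1
}

#' Classify a trend by its likelihood statistic
#'
#' Maps a bootstrap trend likelihood and slope sign onto the standard
#' categories: "likely" above 0.85, "somewhat likely" from 0.70 to 0.85, and
#' "as likely as not" below 0.70. Both interval endpoints (0.70 and 0.85)
#' fall in "somewhat likely" (intervals closed on the lower side).
#'
#' @param likelihood Trend likelihood in \[0, 1\].
#' @param slope_sign Sign of the estimated slope (+1/-1, or any signed slope).
#' @return One of `"likely up"`, `"likely down"`, `"somewhat likely up"`,
#'   `"somewhat likely down"`, `"as likely as not"`.
#' @examples
#' classify_trend_likelihood(0.90, +1)  # "likely up"
#' classify_trend_likelihood(0.75, -1)  # "somewhat likely down"
#' classify_trend_likelihood(0.50, +1)  # "as likely as not"
#' @export
classify_trend_likelihood <- function(likelihood, slope_sign) {
  if (is.na(likelihood) || likelihood < 0 || likelihood > 1) {
    stop("likelihood must lie in [0, 1]", call. = FALSE)
  }
  dir <- if (sign(slope_sign) >= 0) "up" else "down"
  if (likelihood > 0.85) {
    paste("likely", dir)
  } else if (likelihood >= 0.70) {
    paste("somewhat likely", dir)
  } else {
    "as likely as not"
  }
}

#' Bootstrap trend likelihood for an annual series
#'
#' A simple annual-series stand-in for the load-model bootstrap used with
#' flow-normalized trends: resample (year, value) pairs with replacement,
#' re-estimate the Theil-Sen slope, and report the fraction of resampled
#' slopes sharing the sign of the full-sample slope. Resamples with fewer
#' than 3 distinct years, or a resampled slope of exactly zero, count as
#' non-supporting.
#'
#' @param series An [annual_series()] with >= 10 points.
#' @param n_boot Number of bootstrap resamples (>= 200).
#' @param seed Integer seed; required, so runs are reproducible.
#' @return Likelihood in \[0, 1\]. A constant (zero-slope) series returns 0.5
#'   with a warning.
#' @export
bootstrap_trend_likelihood <- function(series, n_boot = 1000, seed) {
  keep <- !is.na(series$value)
  yr <- series$year[keep]
  v <- series$value[keep]
  if (length(v) < 10L) stop("need at least 10 points", call. = FALSE)
  if (n_boot < 200L) stop("n_boot must be at least 200", call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)

  full <- theil_sen(annual_series(yr, v))$slope
  if (full == 0) {
    warning("series has zero Theil-Sen slope; likelihood set to 0.5")
    return(0.5)
  }
  n <- length(v)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  hits <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    uy <- unique(yr[idx])
    if (length(uy) < 3L) next
    # collapse duplicate years (mean) so pairwise slopes stay defined
    vv <- tapply(v[idx], yr[idx], mean)
    if (length(vv) < 3L) next
    sl <- theil_sen(annual_series(as.integer(names(vv)), as.numeric(vv)))$slope
    if (sign(sl) == sign(full)) hits <- hits + 1L
  }
  hits / n_boot
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
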
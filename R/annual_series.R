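#' Annual time series
#'
#' The universal currency of the pipeline: one value per calendar year with
#' units. Stored as a plain two-column data frame (`year`, `value`) with a
#' `units` attribute, so it round-trips through CSV without ceremony.
#'
#' @param year Integer vector of calendar years. Must be unique; stored sorted.
#' @param value Numeric vector, same length as `year`. `NA` is allowed and
#'   marks a flagged missing year; non-finite values (`Inf`, `NaN`) are not.
#' @param units Unit string, default `"kg km-2 yr-1"` (areal mass flux).
#'
#' @return An object of class `annual_series` (a data frame).
#' @examples
#' annual_series(1950:1959, seq(100, 1000, by = 100))
#' @export
annual_series <- function(year, value, units = "kg km-2 yr-1") {
  if (length(year) != length(value)) {
    stop("`year` and `value` must have the same length", call. = FALSE)
  }
  year <- as.integer(year)
  if (anyNA(year)) stop("`year` must not contain NA", call. = FALSE)
  if (anyDuplicated(year)) stop("years must be unique", call. = FALSE)
  value <- as.numeric(value)
  bad <- !is.na(value) & !is.finite(value)
  if (any(bad)) {
    stop("non-finite values at years: ", paste(year[bad], collapse = ", "),
         call. = FALSE)
  }
  ord <- order(year)
  out <- data.frame(year = year[ord], value = value[ord])
  attr(out, "units") <- units
  class(out) <- c("annual_series", "data.frame")
  out
}

#' Coerce to an annual series
#'
#' @param x A data frame with a `year` column and one value column, or an
#'   `annual_series` (returned unchanged).
#' @param value_col Name of the value column; defaults to the first non-year
#'   column.
#' @param units Units to attach.
#' @return An `annual_series`.
#' @export
as_annual_series <- function(x, value_col = NULL, units = "kg km-2 yr-1") {
  if (inherits(x, "annual_series")) return(x)
  if (!is.data.frame(x) || !"year" %in% names(x)) {
    stop("need a data frame with a `year` column", call. = FALSE)
  }
  if (is.null(value_col)) {
    value_col <- setdiff(names(x), "year")[1]
    if (is.na(value_col)) stop("no value column found", call. = FALSE)
  }
  annual_series(x$year, x[[value_col]], units = units)
}

#' @export
print.annual_series <- function(x, ...) {
  cat(sprintf("<annual_series> %d years (%d-%d), units: %s\n",
              nrow(x), min(x$year), max(x$year), series_units(x)))
  print.data.frame(utils::head(as.data.frame(x), 8), row.names = FALSE)
  if (nrow(x) > 8) cat("  ... ", nrow(x) - 8, " more years\n", sep = "")
  invisible(x)
}

#' Units of an annual series
#' @param x An `annual_series`.
#' @return The unit string.
#' @export
series_units <- function(x) attr(x, "units") %||% "kg km-2 yr-1"

#' Look up series values by year
#'
#' @param x An `annual_series`.
#' @param years Years to extract.
#' @param strict Error if a requested year is absent (default); otherwise NA.
#' @return Numeric vector aligned with `years`.
#' @export
series_value <- function(x, years, strict = TRUE) {
  idx <- match(as.integer(years), x$year)
  if (strict && anyNA(idx)) {
    stop("years not in series: ",
         paste(years[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  x$value[idx]
}

#' Restrict an annual series to a span of years
#'
#' @param x An `annual_series`.
#' @param from,to First and last year to keep (inclusive).
#' @return An `annual_series` covering `[from, to]`.
#' @export
series_window <- function(x, from = -Inf, to = Inf) {
  keep <- x$year >= from & x$year <= to
  annual_series(x$year[keep], x$value[keep], units = series_units(x))
}

# intersect two series on common years; returns list(year, a, b)
align_series <- function(a, b) {
  years <- intersect(a$year, b$year)
  if (length(years) == 0L) stop("series share no years", call. = FALSE)
  years <- sort(years)
  list(year = years,
       a = series_value(a, years),
       b = series_value(b, years))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
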
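#' Read an annual series from CSV
#'
#' Expects a `year` column plus one value column (any name; the first
#' non-year column is used unless `value_col` is given).
#'
#' @param path CSV path.
#' @param value_col Optional value column name.
#' @param units Units to attach.
#' @return An [annual_series()].
#' @export
read_annual_series <- function(path, value_col = NULL,
                               units = "kg km-2 yr-1") {
  as_annual_series(utils::read.csv(path), value_col = value_col,
                   units = units)
}

#' Write an annual series to CSV
#'
#' @param x An [annual_series()].
#' @param path Output path.
#' @param value_col Header for the value column.
#' @export
write_annual_series <- function(x, path, value_col = "value") {
  df <- data.frame(year = x$year, v = x$value)
  names(df)[2] <- value_col
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a balance-component table from CSV
#'
#' Expects `year` plus component columns named as in [balance_components()]
#' (`fertilizer` or `fertilizer_farm`/`fertilizer_nonfarm`, `manure`,
#' `wastewater`, `fixation`, `atmospheric_deposition_oxidized`, `weathering`,
#' `crop_uptake`, ...), in kg km-2 yr-1.
#'
#' @param path CSV path.
#' @param nutrient `"N"` or `"P"`.
#' @return A [balance_components()] table.
#' @export
read_components_csv <- function(path, nutrient = c("N", "P")) {
  balance_components(utils::read.csv(path), nutrient = match.arg(nutrient))
}

#' Write a balance-component table to CSV
#' @param components A [balance_components()] table.
#' @param path Output path.
#' @export
write_components_csv <- function(components, path) {
  utils::write.csv(as.data.frame(components), path, row.names = FALSE)
  invisible(path)
}

#' Read a crop table from CSV
#'
#' Expects columns `crop, year, yield, content_n, content_p, is_n_fixing`;
#' the nutrient selects which content column becomes the table's factor.
#'
#' @param path CSV path.
#' @param nutrient `"N"` or `"P"`.
#' @return A [crop_table()].
#' @export
read_crop_csv <- function(path, nutrient = c("N", "P")) {
  nutrient <- match.arg(nutrient)
  df <- utils::read.csv(path)
  cc <- if (nutrient == "N") "content_n" else "content_p"
  if (!cc %in% names(df)) stop("crop CSV lacks column ", cc, call. = FALSE)
  crop_table(data.frame(crop = df$crop, year = df$year, yield = df$yield,
                        content = df[[cc]],
                        is_n_fixing = as.logical(df$is_n_fixing)),
             nutrient = nutrient)
}

#' Persist synthetic truth as a flat key-value file
#'
#' One `key = value` pair per line: `lag_<k>` entries, `year_poly_<d>`
#' entries, `intercept`, `noise_sd`, `ar1_phi_components`,
#' `year_index_origin`, `seed`.
#'
#' @param truth A [synthetic_truth()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  lines <- c(
    sprintf("lag_%s = %.17g", names(truth$lag_coefficients),
            truth$lag_coefficients),
    if (length(truth$year_poly_coefficients)) {
      sprintf("year_poly_%d = %.17g",
              seq_along(truth$year_poly_coefficients),
              truth$year_poly_coefficients)
    },
    sprintf("intercept = %.17g", truth$intercept),
    sprintf("noise_sd = %.17g", truth$noise_sd),
    sprintf("ar1_phi_components = %.17g", truth$ar1_phi_components),
    sprintf("year_index_origin = %d", truth$year_index_origin),
    sprintf("seed = %d", truth$seed))
  writeLines(lines, path)
  invisible(path)
}

#' Read synthetic truth back from its key-value file
#' @param path Path written by [write_truth()].
#' @return A [synthetic_truth()].
#' @export
read_truth <- function(path) {
  lines <- readLines(path)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1L)
  vals <- as.numeric(vapply(kv, `[`, "", 2L))
  lag_i <- grep("^lag_", keys)
  poly_i <- grep("^year_poly_", keys)
  poly <- vals[poly_i][order(as.integer(sub("year_poly_", "", keys[poly_i])))]
  lagc <- stats::setNames(vals[lag_i], sub("lag_", "", keys[lag_i]))
  synthetic_truth(
    lag_coefficients = lagc[order(as.integer(names(lagc)))],
    year_poly_coefficients = poly,
    intercept = vals[keys == "intercept"],
    noise_sd = vals[keys == "noise_sd"],
    ar1_phi_components = vals[keys == "ar1_phi_components"],
    year_index_origin = vals[keys == "year_index_origin"],
    seed = vals[keys == "seed"])
}
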
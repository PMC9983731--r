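#' Annual watershed nutrient retention
#'
#' Retention is the percent of the annual nutrient balance not exported in
#' the river load: `(1 - load / balance) * 100`, computed on the years the
#' two series share. Years with a zero or negative balance get a missing
#' retention (the ratio is undefined or uninterpretable there) and a warning.
#'
#' The operation is agnostic to which load series is passed (flow-normalized
#' or Kalman-filter annual loads); the caller chooses.
#'
#' @param load River load [annual_series()], kg km-2 yr-1.
#' @param balance Nutrient balance [annual_series()], kg km-2 yr-1.
#' @return A `retention_series` data frame: `year`, `load`, `balance`,
#'   `retention` (percent).
#' @examples
#' r <- compute_retention(annual_series(2000, 300), annual_series(2000, 1000))
#' r$retention  # 70
#' @export
compute_retention <- function(load, balance) {
  al <- align_series(load, balance)
  ret <- ifelse(!is.na(al$b) & al$b > 0,
                (1 - al$a / al$b) * 100,
                NA_real_)
  bad <- !is.na(al$b) & al$b <= 0
  if (any(bad)) {
    warning(sum(bad), " year(s) with balance <= 0: retention undefined, ",
            "set to NA (years ", paste(al$year[bad], collapse = ", "), ")")
  }
  out <- data.frame(year = al$year, load = al$a, balance = al$b,
                    retention = ret)
  class(out) <- c("retention_series", "data.frame")
  out
}

#' Areal river load
#'
#' Convert a whole-river mass load to common areal units by dividing by the
#' upstream drainage area.
#'
#' @param mass_load Load in kg yr-1.
#' @param drainage_area Upstream drainage area in km2 (> 0).
#' @return Load in kg km-2 yr-1.
#' @examples
#' areal_load(2.888e9, 2887854)  # ~1000 kg km-2 yr-1
#' @export
areal_load <- function(mass_load, drainage_area) {
  if (any(drainage_area <= 0)) stop("drainage area must be positive",
                                    call. = FALSE)
  mass_load / drainage_area
}

#' TN:TP molar ratio
#'
#' Converts total N and total P concentrations (mg L-1 as N and as P) to a
#' molar ratio using the molecular weights of the elements. The default P
#' molar mass is the atomic weight 30.974 g mol-1; some published analyses
#' round it to 32, so `m_p` is overridable for literal replication of such
#' results.
#'
#' @param tn_conc TN concentration, mg L-1 as N.
#' @param tp_conc TP concentration, mg L-1 as P (> 0).
#' @param m_n Molar mass of N, g mol-1.
#' @param m_p Molar mass of P, g mol-1.
#' @return Unitless molar ratio (vectorized).
#' @examples
#' molar_ratio(2.8, 0.31, m_p = 30.974)  # ~20
#' @export
molar_ratio <- function(tn_conc, tp_conc, m_n = 14.007, m_p = 30.974) {
  if (any(tp_conc <= 0)) stop("TP concentration must be positive",
                              call. = FALSE)
  (tn_conc / m_n) / (tp_conc / m_p)
}
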
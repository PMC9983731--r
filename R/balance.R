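#' Stated constants of the mass-balance model
#'
#' Fixed rates used by the annual watershed balance: the fraction of applied
#' fertilizer + manure N emitted as N2O from agricultural soils, the N2:N2O
#' molar-flux ratio used to scale complete denitrification, the constant
#' phosphorus rock-weathering input, and the constant riverine N surface
#' emission. All overridable per call; these are the defaults the
#' period-of-record balance uses.
#'
#' @format Named numeric vector with elements `n2o_fraction` (0.01, unitless),
#'   `n2_to_n2o` (1.7, unitless), `p_weathering` (7.16 kg km-2 yr-1),
#'   `river_n_emission` (114 kg km-2 yr-1).
#' @export
balance_constants <- c(
  n2o_fraction     = 0.01,
  n2_to_n2o        = 1.7,
  p_weathering     = 7.16,
  river_n_emission = 114
)

# component roster by nutrient; order is also the CSV column order
.n_inputs  <- c("fertilizer", "manure", "wastewater", "fixation",
                "atmospheric_deposition_oxidized")
.n_outputs <- c("crop_uptake", "n2o_emission", "n2_emission", "river_emission")
.p_inputs  <- c("fertilizer", "manure", "wastewater", "weathering")
.p_outputs <- c("crop_uptake")

#' Per-year balance component ledger
#'
#' Holds the annual input/output components of the watershed mass balance for
#' one nutrient. Nitrogen tables carry fertilizer, manure, wastewater effluent,
#' biological fixation, oxidized atmospheric deposition (the reduced forms are
#' deliberately excluded from the balance: ammonia and organic N deposition
#' are treated as same-year recycling of local agricultural emissions, and a
#' `atmospheric_deposition_reduced` column, if present, is kept for reference
#' only), crop uptake, and the gaseous/riverine emission outputs. Phosphorus
#' tables carry fertilizer, manure, wastewater, rock weathering, and crop
#' uptake.
#'
#' Missing `n2o_emission`/`n2_emission` columns are derived from fertilizer and
#' manure by [compute_balance()]; missing `river_emission` (N) and `weathering`
#' (P) default to the stated constants. Fertilizer may be given pre-summed or
#' split as `fertilizer_farm` + `fertilizer_nonfarm` (summed on construction).
#'
#' @param data Data frame with a `year` column and component columns in
#'   kg km-2 yr-1.
#' @param nutrient `"N"` or `"P"`.
#' @return A `balance_components` data frame with a `nutrient` attribute.
#' @export
balance_components <- function(data, nutrient = c("N", "P")) {
  nutrient <- match.arg(nutrient)
  if (!is.data.frame(data) || !"year" %in% names(data)) {
    stop("`data` must be a data frame with a `year` column", call. = FALSE)
  }
  data <- as.data.frame(data)
  if (all(c("fertilizer_farm", "fertilizer_nonfarm") %in% names(data)) &&
      !"fertilizer" %in% names(data)) {
    data$fertilizer <- data$fertilizer_farm + data$fertilizer_nonfarm
  }
  year <- as.integer(data$year)
  if (anyDuplicated(year)) stop("duplicate years", call. = FALSE)
  if (is.unsorted(year)) data <- data[order(year), , drop = FALSE]
  year <- sort(year)
  if (length(year) > 1L && any(diff(year) != 1L)) {
    stop("years must be consecutive with no gaps", call. = FALSE)
  }
  wrong <- if (nutrient == "P") {
    intersect(names(data), c("fixation", "atmospheric_deposition_oxidized",
                             "atmospheric_deposition_reduced", "n2o_emission",
                             "n2_emission", "river_emission"))
  } else {
    intersect(names(data), "weathering")
  }
  if (length(wrong)) {
    stop(nutrient, " table carries components of the other nutrient: ",
         paste(wrong, collapse = ", "), call. = FALSE)
  }
  comp_cols <- setdiff(names(data), "year")
  for (cc in comp_cols) {
    v <- data[[cc]]
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      stop("component `", cc, "` must be finite numeric", call. = FALSE)
    }
    if (any(v < 0)) {
      stop("component `", cc, "` has negative values; components are ",
           "physically nonnegative", call. = FALSE)
    }
  }
  attr(data, "nutrient") <- nutrient
  class(data) <- c("balance_components", "data.frame")
  data
}

#' @export
print.balance_components <- function(x, ...) {
  cat(sprintf("<balance_components> nutrient %s, %d years (%d-%d)\n",
              attr(x, "nutrient"), nrow(x), min(x$year), max(x$year)))
  cat("components:", paste(setdiff(names(x), "year"), collapse = ", "), "\n")
  invisible(x)
}

#' Crop yield and nutrient-content table
#'
#' Per-crop annual yields with constant nutrient content factors, the basis of
#' the crop-uptake output term. The content factor converts the crop's yield
#' unit to kg of nutrient, and is held constant over years; `is_n_fixing`
#' marks legumes and other N-fixing crops whose biological fixation input is
#' set equal to their harvest-N removal.
#'
#' @param data Data frame with columns `crop`, `year`, `yield`
#'   (crop units km-2 yr-1), `content` (kg nutrient per crop unit), and
#'   `is_n_fixing` (logical).
#' @param nutrient `"N"` or `"P"` - which nutrient the `content` column is for.
#' @return A `crop_table` data frame with a `nutrient` attribute.
#' @export
crop_table <- function(data, nutrient = c("N", "P")) {
  nutrient <- match.arg(nutrient)
  need <- c("crop", "year", "yield", "content", "is_n_fixing")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("crop table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  data <- as.data.frame(data)[need]
  if (any(data$yield < 0) || anyNA(data$yield)) {
    stop("yields must be nonnegative and non-missing", call. = FALSE)
  }
  if (any(data$content <= 0) || anyNA(data$content)) {
    stop("every crop needs a positive content factor", call. = FALSE)
  }
  # content constant per crop across years
  by_crop <- tapply(data$content, data$crop, function(v) length(unique(v)))
  if (any(by_crop > 1L)) {
    stop("nutrient content must be constant over years for each crop",
         call. = FALSE)
  }
  data$is_n_fixing <- as.logical(data$is_n_fixing)
  attr(data, "nutrient") <- nutrient
  class(data) <- c("crop_table", "data.frame")
  data
}

#' Annual crop nutrient uptake
#'
#' The primary output of the balance: harvest removal, estimated per year as
#' the sum over crops of yield times nutrient content.
#'
#' @param crops A [crop_table()].
#' @return An [annual_series()] of uptake in kg km-2 yr-1.
#' @examples
#' ct <- crop_table(data.frame(crop = "corn", year = 2000, yield = 100,
#'                             content = 0.5, is_n_fixing = FALSE), "N")
#' compute_crop_uptake(ct)  # 50
#' @export
compute_crop_uptake <- function(crops) {
  stopifnot(inherits(crops, "crop_table"))
  up <- tapply(crops$yield * crops$content, crops$year, sum)
  annual_series(as.integer(names(up)), as.numeric(up))
}

#' Annual biological N fixation
#'
#' Fixation input for N-fixing crops, set equal to their nitrogen uptake and
#' removal in harvest (yield times N content, summed over fixing crops).
#'
#' @param crops A [crop_table()] with `nutrient = "N"`.
#' @return An [annual_series()] of fixation in kg km-2 yr-1 (zero in years
#'   with no fixing-crop harvest).
#' @export
compute_n_fixation <- function(crops) {
  stopifnot(inherits(crops, "crop_table"))
  if (attr(crops, "nutrient") != "N") {
    stop("N fixation is defined for the nitrogen crop table only",
         call. = FALSE)
  }
  years <- sort(unique(crops$year))
  fix <- crops[crops$is_n_fixing, , drop = FALSE]
  out <- setNames(numeric(length(years)), years)
  if (nrow(fix)) {
    s <- tapply(fix$yield * fix$content, fix$year, sum)
    out[names(s)] <- as.numeric(s)
  }
  annual_series(years, as.numeric(out))
}

#' Gaseous N outputs from agricultural soils
#'
#' Agricultural N2O flux is 1% of fertilizer plus manure N; complete
#' denitrification to N2 is that flux scaled by the literature N2:N2O ratio
#' of 1.7.
#'
#' @param fertilizer,manure [annual_series()] of applied N, kg km-2 yr-1.
#' @param n2o_fraction Fraction of (fertilizer + manure) emitted as N2O.
#' @param n2_to_n2o N2:N2O ratio.
#' @return List with `n2o` and `n2` [annual_series()].
#' @examples
#' f <- annual_series(2000, 600); m <- annual_series(2000, 400)
#' compute_n_gaseous_outputs(f, m)  # n2o = 10, n2 = 17
#' @export
compute_n_gaseous_outputs <- function(fertilizer, manure,
                                      n2o_fraction = balance_constants[["n2o_fraction"]],
                                      n2_to_n2o = balance_constants[["n2_to_n2o"]]) {
  al <- align_series(fertilizer, manure)
  if (!setequal(fertilizer$year, manure$year)) {
    stop("fertilizer and manure series must cover the same years",
         call. = FALSE)
  }
  n2o <- n2o_fraction * (al$a + al$b)
  list(n2o = annual_series(al$year, n2o),
       n2  = annual_series(al$year, n2_to_n2o * n2o))
}

#' Annual watershed nutrient balance
#'
#' Inputs minus outputs, per year. For nitrogen:
#' `(fertilizer + manure + wastewater + fixation + oxidized deposition) -
#' (crop uptake + N2O + N2 + riverine emission)`; reduced deposition is never
#' summed. For phosphorus:
#' `(fertilizer + manure + wastewater + weathering) - crop uptake`.
#'
#' Missing N gaseous-emission columns are derived from fertilizer + manure via
#' the 1% and 1.7x rules; a missing riverine N emission defaults to the
#' constant 114 kg km-2, and missing P weathering to 7.16 kg km-2 yr-1.
#' Instead of the constant, riverine N emission can be computed as a fraction
#' of the N delivered to rivers (inputs minus land outputs) by passing
#' `river_emission_rate` (e.g. 0.19); the constant remains the default because
#' the rate definition is circular in the source accounting.
#'
#' Negative balances (deficiency: outputs exceed inputs) are meaningful and
#' allowed, but reported via a message so runs are auditable.
#'
#' @param components A [balance_components()] table.
#' @param river_emission Constant riverine N emission, kg km-2 yr-1, used when
#'   the table has no `river_emission` column and no rate is given.
#' @param river_emission_rate Optional fraction of net N delivery emitted from
#'   river surfaces; overrides the constant when non-`NULL`.
#' @param p_weathering Constant P weathering input, kg km-2 yr-1, used when
#'   the P table has no `weathering` column.
#' @param n2o_fraction,n2_to_n2o Gaseous-emission rule constants, used when
#'   the N table lacks `n2o_emission`/`n2_emission` columns.
#' @param quiet Suppress the negative-balance message.
#' @return An [annual_series()] of the balance (kg km-2 yr-1).
#' @export
compute_balance <- function(components,
                            river_emission = balance_constants[["river_n_emission"]],
                            river_emission_rate = NULL,
                            p_weathering = balance_constants[["p_weathering"]],
                            n2o_fraction = balance_constants[["n2o_fraction"]],
                            n2_to_n2o = balance_constants[["n2_to_n2o"]],
                            quiet = FALSE) {
  stopifnot(inherits(components, "balance_components"))
  nutrient <- attr(components, "nutrient")
  x <- as.data.frame(components)
  n <- nrow(x)

  col <- function(nm) if (nm %in% names(x)) x[[nm]] else NULL

  if (nutrient == "N") {
    if (is.null(col("n2o_emission"))) {
      fm <- col("fertilizer")
      mn <- col("manure")
      if (is.null(fm) || is.null(mn)) {
        stop("need fertilizer and manure to derive gaseous emissions",
             call. = FALSE)
      }
      x$n2o_emission <- n2o_fraction * (fm + mn)
      x$n2_emission <- n2_to_n2o * x$n2o_emission
    } else if (is.null(col("n2_emission"))) {
      x$n2_emission <- n2_to_n2o * x$n2o_emission
    }
    inputs <- .n_inputs
    need <- setdiff(inputs, names(x))
    if (length(need)) {
      stop("missing N component column(s): ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    if (is.null(col("crop_uptake"))) {
      stop("missing N component column(s): crop_uptake", call. = FALSE)
    }
    input_sum <- Reduce(`+`, x[inputs])
    land_out <- x$crop_uptake + x$n2o_emission + x$n2_emission
    if (is.null(col("river_emission"))) {
      x$river_emission <- if (!is.null(river_emission_rate)) {
        pmax(river_emission_rate * (input_sum - land_out), 0)
      } else {
        rep(river_emission, n)
      }
    }
    bal <- input_sum - (land_out + x$river_emission)
  } else {
    if (is.null(col("weathering"))) x$weathering <- rep(p_weathering, n)
    need <- setdiff(c(.p_inputs, .p_outputs), names(x))
    if (length(need)) {
      stop("missing P component column(s): ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    bal <- Reduce(`+`, x[.p_inputs]) - x$crop_uptake
  }

  if (!quiet && any(bal < 0)) {
    message(sum(bal < 0), " year(s) with negative ", nutrient,
            " balance (nutrient deficiency)")
  }
  annual_series(x$year, bal)
}
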
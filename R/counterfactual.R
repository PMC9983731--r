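#' Counterfactual regressor designs
#'
#' Builds the hypothetical-input design for the two impact scenarios run
#' against a calibrated load model:
#'
#' * **Scenario A** freezes the nutrient-balance regressors at their
#'   baseline-year levels: each selected `lag<k>` column takes, for every
#'   prediction year, the value it had in `freeze_year` (i.e. the balance of
#'   calendar year `freeze_year - k`). Year terms are untouched. This asks
#'   how loads would have evolved with no variability in nutrient balances
#'   after the baseline.
#' * **Scenario B** freezes the latent year terms: each `year<d>` column
#'   takes its `freeze_year` value (`tau(freeze_year)^d`) in every year,
#'   with balance columns untouched. This asks how loads would have evolved
#'   with no variability in latent watershed processes.
#'
#' "Frozen at baseline levels" is interpreted per regressor (each lag keeps
#' its own baseline value). The alternative reading — every lag column set
#' to the balance of the baseline year itself — is available as
#' `freeze_mode = "common"`, which requires the `balance` series.
#'
#' @param design The [build_design()] the model was fitted on.
#' @param model The fitted `attribution_model`.
#' @param scenario `"A"` (freeze balances) or `"B"` (freeze year terms).
#' @param freeze_year Baseline calendar year; defaults to the design's year
#'   index origin (the first load year).
#' @param freeze_mode `"per_lag"` (default) or `"common"` (scenario A only).
#' @param balance Balance [annual_series()], needed for
#'   `freeze_mode = "common"`.
#' @return A `lag_design` with the frozen columns.
#' @export
scenario_design <- function(design, model, scenario = c("A", "B"),
                            freeze_year = design$year_index_origin,
                            freeze_mode = c("per_lag", "common"),
                            balance = NULL) {
  stopifnot(inherits(design, "lag_design"),
            inherits(model, "attribution_model"))
  scenario <- match.arg(scenario)
  freeze_mode <- match.arg(freeze_mode)
  if (!freeze_year %in% design$years) {
    stop("freeze year ", freeze_year, " is not a prediction year of the design",
         call. = FALSE)
  }
  X <- design$X
  row0 <- match(freeze_year, design$years)
  sel <- model$selected_terms
  if (scenario == "A") {
    lag_cols <- grep("^lag[0-9]+$", sel, value = TRUE)
    for (cc in lag_cols) {
      X[, cc] <- if (freeze_mode == "common") {
        if (is.null(balance)) {
          stop("freeze_mode = \"common\" needs the balance series",
               call. = FALSE)
        }
        series_value(balance, freeze_year)
      } else {
        X[row0, cc]
      }
    }
  } else {
    year_cols <- grep("^year[0-9]$", sel, value = TRUE)
    for (cc in year_cols) X[, cc] <- X[row0, cc]
  }
  out <- design
  out$X <- X
  out
}

#' Predict annual loads from a fitted attribution model
#'
#' Evaluates `intercept + sum(coefficient * column)` per year on a design —
#' the original design reproduces the OLS fitted values; a
#' [scenario_design()] yields the counterfactual trajectory.
#'
#' @param object A fitted `attribution_model`.
#' @param design A `lag_design` whose columns cover the selected terms;
#'   defaults to the design the model was fitted on.
#' @param ... Unused.
#' @return An [annual_series()] of predicted loads.
#' @export
predict.attribution_model <- function(object, design = object$design, ...) {
  stopifnot(inherits(design, "lag_design"))
  miss <- setdiff(object$selected_terms, colnames(design$X))
  if (length(miss)) {
    stop("design lacks selected terms: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pred <- rep(unname(object$coefficients["(Intercept)"]), length(design$years))
  for (tm in object$selected_terms) {
    pred <- pred + unname(object$coefficients[tm]) * design$X[, tm]
  }
  annual_series(design$years, pred, units = design$units)
}

#' Windowed impact summary of a counterfactual scenario
#'
#' Compares mean annual counterfactual predictions with the original model
#' predictions over an impact window (default the final five years,
#' 2013-2017): window means, their absolute difference, and the percent
#' difference `100 * (counterfactual - original) / original`.
#'
#' @param original Original-model predictions, an [annual_series()].
#' @param counterfactual Scenario predictions, an [annual_series()].
#' @param window Length-2 integer vector `(start, end)`, inclusive.
#' @param scenario Optional label (`"A"`, `"B"`, ...) carried into the result.
#' @return A `scenario_result` list: `scenario`, `impact_window`,
#'   `original_mean`, `counterfactual_mean`, `delta` (kg km-2), and
#'   `delta_percent`.
#' @export
impact_summary <- function(original, counterfactual, window = c(2013, 2017),
                           scenario = NA_character_) {
  window <- as.integer(window)
  stopifnot(length(window) == 2L, window[1] <= window[2])
  years <- window[1]:window[2]
  if (!all(years %in% original$year) || !all(years %in% counterfactual$year)) {
    stop("impact window not fully covered by both series", call. = FALSE)
  }
  om <- mean(series_value(original, years))
  cm <- mean(series_value(counterfactual, years))
  structure(
    list(scenario = scenario,
         impact_window = window,
         original_mean = om,
         counterfactual_mean = cm,
         delta = cm - om,
         delta_percent = 100 * (cm - om) / om),
    class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("<scenario_result>%s window %d-%d\n",
              if (is.na(x$scenario)) "" else paste0(" scenario ", x$scenario),
              x$impact_window[1], x$impact_window[2]))
  cat(sprintf("  original mean %.1f, counterfactual mean %.1f (delta %+.1f, %+.1f%%)\n",
              x$original_mean, x$counterfactual_mean, x$delta,
              x$delta_percent))
  invisible(x)
}

#' Run both counterfactual scenarios for a fitted model
#'
#' Convenience wrapper: builds scenario A and B designs, predicts, and
#' summarizes impacts over the window.
#'
#' @inheritParams scenario_design
#' @inheritParams impact_summary
#' @return List with `original` (predictions), `A` and `B` (each a list of
#'   `predictions` and `impact`).
#' @export
run_counterfactuals <- function(model, design = model$design,
                                freeze_year = design$year_index_origin,
                                window = c(2013, 2017)) {
  orig <- predict(model, design)
  out <- list(original = orig)
  for (sc in c("A", "B")) {
    d <- scenario_design(design, model, sc, freeze_year = freeze_year)
    pred <- predict(model, d)
    out[[sc]] <- list(predictions = pred,
                      impact = impact_summary(orig, pred, window,
                                              scenario = sc))
  }
  out
}
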
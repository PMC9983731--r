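#' AR(1) pre-whitening of an annual series
#'
#' Fits a lag-1 autoregression by Yule-Walker (the lag-1 autocorrelation of
#' the series) and returns the AR(1) residuals, `r(t) = y(t) - phi * y(t-1)`,
#' which reduce the series toward white noise before lag-correlation
#' screening. The residual series starts at the second year.
#'
#' @param series An [annual_series()] with at least 10 points and no gaps.
#' @return List with `residuals` (an [annual_series()] of length n-1) and
#'   `phi` (the lag-1 autocorrelation).
#' @export
prewhiten_ar1 <- function(series) {
  v <- series$value
  yr <- series$year
  if (anyNA(v)) stop("pre-whitening requires a gap-free series", call. = FALSE)
  if (length(v) < 10L) stop("need at least 10 points", call. = FALSE)
  if (any(diff(yr) != 1L)) stop("years must be consecutive", call. = FALSE)
  if (stats::sd(v) == 0) stop("phi undefined for a constant series",
                              call. = FALSE)
  d <- v - mean(v)
  phi <- sum(d[-1] * d[-length(d)]) / sum(d^2)
  res <- v[-1] - phi * v[-length(v)]
  list(residuals = annual_series(yr[-1], res, units = series_units(series)),
       phi = phi)
}

#' Screen candidate balance lags by correlation with load residuals
#'
#' For each lag `k` in `0..max_lag`, computes the Pearson correlation between
#' the (pre-whitened) load series and the nutrient balance shifted back by
#' `k` years, over the years both provide. Lags pass the screen under
#' `mode = "positive_and_significant"` if `r > 0` with a two-sided p-value
#' below `alpha` (the nitrogen rule), or under `mode = "positive_only"` if
#' simply `r > 0` (the phosphorus rule).
#'
#' @param load_residuals Pre-whitened load [annual_series()] (see
#'   [prewhiten_ar1()]); raw loads may be passed, but screening on whitened
#'   residuals is the intended use.
#' @param balance Nutrient-balance [annual_series()].
#' @param max_lag Largest lag considered, limited by the balance history
#'   (default and ceiling 25 years).
#' @param mode Screening rule (see above).
#' @param alpha Significance level for the two-sided correlation test.
#' @return Integer vector of admitted lags, in increasing order, with the
#'   full per-lag table (`lag`, `n`, `r`, `p`) as attribute `"screen"`.
#' @export
lag_correlation_screen <- function(load_residuals, balance, max_lag = 25,
                                   mode = c("positive_and_significant",
                                            "positive_only"),
                                   alpha = 0.05) {
  mode <- match.arg(mode)
  if (max_lag < 0 || max_lag > 25) stop("max_lag must be in 0..25",
                                        call. = FALSE)
  lags <- 0:max_lag
  tab <- data.frame(lag = lags, n = NA_integer_, r = NA_real_, p = NA_real_)
  for (i in seq_along(lags)) {
    k <- lags[i]
    shifted <- annual_series(balance$year + k, balance$value)
    years <- intersect(load_residuals$year, shifted$year)
    if (length(years) < 4L) {
      warning("lag ", k, " skipped: fewer than 4 overlapping years")
      next
    }
    x <- series_value(load_residuals, years)
    y <- series_value(shifted, years)
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 4L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      warning("lag ", k, " skipped: degenerate overlap")
      next
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    tab$n[i] <- sum(ok)
    tab$r[i] <- unname(ct$estimate)
    tab$p[i] <- ct$p.value
  }
  pass <- switch(mode,
    positive_and_significant = !is.na(tab$r) & tab$r > 0 & tab$p < alpha,
    positive_only            = !is.na(tab$r) & tab$r > 0)
  out <- tab$lag[pass]
  attr(out, "screen") <- tab
  out
}

#' Build the lagged-regression design
#'
#' Assembles the response (annual river load) and the regressor matrix of
#' lagged balances (`lag<k>` columns: balance shifted back `k` years) and
#' indexed-year polynomial terms (`year1`, `year2`, `year3`: tau, tau^2,
#' tau^3 with `tau = year - year_index_origin`). Rows are trimmed to years
#' with complete coverage across all candidate lags.
#'
#' @param load Response [annual_series()] (flow-normalized load).
#' @param balance Nutrient-balance [annual_series()].
#' @param candidate_lags Integer set within 0..25.
#' @param max_year_degree Highest year-polynomial degree offered (0..3).
#' @param year_index_origin Calendar year where tau = 0; defaults to the
#'   first load year.
#' @return A `lag_design` list: `years`, `response`, `X` (named matrix),
#'   `year_index_origin`, `candidate_lags`, `max_year_degree`.
#' @export
build_design <- function(load, balance, candidate_lags,
                         max_year_degree = 3,
                         year_index_origin = min(load$year)) {
  candidate_lags <- sort(unique(as.integer(candidate_lags)))
  if (length(candidate_lags) && (min(candidate_lags) < 0 ||
                                 max(candidate_lags) > 25)) {
    stop("candidate lags must lie in 0..25", call. = FALSE)
  }
  if (!max_year_degree %in% 0:3) stop("max_year_degree must be 0..3",
                                      call. = FALSE)
  if (length(candidate_lags) == 0L && max_year_degree == 0L) {
    stop("empty design: no candidate lags and no year terms", call. = FALSE)
  }

  years <- load$year[!is.na(load$value)]
  cols <- list()
  keep <- rep(TRUE, length(years))
  for (k in candidate_lags) {
    v <- series_value(balance, years - k, strict = FALSE)
    keep <- keep & !is.na(v)
    cols[[paste0("lag", k)]] <- v
  }
  years <- years[keep]
  if (length(years) == 0L) {
    stop("no load years have complete lagged-balance coverage", call. = FALSE)
  }
  X <- do.call(cbind, c(
    lapply(cols, function(v) v[keep]),
    local({
      tau <- years - year_index_origin
      out <- list()
      for (d in seq_len(max_year_degree)) out[[paste0("year", d)]] <- tau^d
      out
    })))
  rownames(X) <- years
  structure(
    list(years = years,
         response = series_value(load, years),
         X = X,
         year_index_origin = year_index_origin,
         candidate_lags = candidate_lags,
         max_year_degree = max_year_degree,
         units = series_units(load)),
    class = "lag_design")
}

#' @export
print.lag_design <- function(x, ...) {
  cat(sprintf("<lag_design> %d years (%d-%d), %d candidate regressors\n",
              length(x$years), min(x$years), max(x$years), ncol(x$X)))
  cat("  columns:", paste(colnames(x$X), collapse = ", "), "\n")
  cat("  year index origin:", x$year_index_origin, "\n")
  invisible(x)
}

# subsets violating the polynomial hierarchy (year2 without year1, ...)
.hierarchy_ok <- function(terms) {
  if ("year3" %in% terms && !"year2" %in% terms) return(FALSE)
  if ("year2" %in% terms && !"year1" %in% terms) return(FALSE)
  TRUE
}

#' Exhaustive best-subset regression selected by BIC
#'
#' Enumerates every subset of the design's columns up to `max_terms` terms
#' (optionally restricted to hierarchical year polynomials: tau^2 only with
#' tau, tau^3 only with tau^2), fits each by ordinary least squares with an
#' intercept, scores it with `BIC = n*ln(RSS/n) + (k+1)*ln(n)`, and returns
#' the minimum-BIC model. Ties within 1e-9 go to the subset with fewer
#' terms, then to the earliest in lexicographic column order. Rank-deficient
#' subsets are skipped (counted in `n_skipped`).
#'
#' The returned fit carries the usual diagnostics: coefficient table with
#' standard errors, t statistics and two-sided p-values (t distribution,
#' n-k-1 df), standardized coefficients (`b_j * sd(x_j) / sd(y)`), variance
#' inflation factors among the selected terms, R-squared, and residuals.
#'
#' @param design A [build_design()] result.
#' @param max_terms Largest subset size enumerated (default 8).
#' @param enforce_year_hierarchy Keep year polynomials hierarchical
#'   (default `TRUE`).
#' @return An `attribution_model` object.
#' @export
best_subset_bic <- function(design, max_terms = 8,
                            enforce_year_hierarchy = TRUE) {
  stopifnot(inherits(design, "lag_design"))
  y <- design$response
  X <- design$X
  n <- length(y)
  p <- ncol(X)
  if (n < 4L) stop("too few rows to fit", call. = FALSE)
  max_terms <- min(max_terms, p, n - 2L)

  cn <- colnames(X)
  hier_parent <- rep(-1L, p)
  if (enforce_year_hierarchy) {
    for (pair in list(c("year2", "year1"), c("year3", "year2"))) {
      child <- match(pair[1], cn)
      parent <- match(pair[2], cn)
      if (!is.na(child) && !is.na(parent)) hier_parent[child] <- parent - 1L
    }
  }
  res <- .best_subset_search(X, y, as.integer(max_terms),
                             as.integer(hier_parent))
  .fit_attribution_model(design, cn[res$terms],
                         n_skipped = as.integer(res$n_skipped))
}

# refit the selected subset with lm and assemble diagnostics
.fit_attribution_model <- function(design, selected_terms, n_skipped = 0L) {
  y <- design$response
  n <- length(y)
  k <- length(selected_terms)
  if (k > 0) {
    df <- data.frame(.y = y, design$X[, selected_terms, drop = FALSE])
    names(df) <- c(".y", selected_terms)
    fml <- stats::reformulate(selected_terms, response = ".y")
  } else {
    df <- data.frame(.y = y)
    fml <- .y ~ 1
  }
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)
  ct <- sm$coefficients

  sdy <- stats::sd(y)
  std_coef <- if (k > 0) {
    vapply(selected_terms, function(tm) {
      unname(stats::coef(fit)[tm]) * stats::sd(design$X[, tm]) / sdy
    }, numeric(1))
  } else numeric(0)

  vif <- if (k > 1) {
    vapply(selected_terms, function(tm) {
      others <- setdiff(selected_terms, tm)
      r2 <- summary(stats::lm(
        stats::reformulate(others, response = tm), data = df))$r.squared
      1 / (1 - r2)
    }, numeric(1))
  } else if (k == 1) {
    stats::setNames(1, selected_terms)
  } else numeric(0)

  rss <- sum(stats::residuals(fit)^2)
  structure(
    list(selected_terms = selected_terms,
         coefficients = stats::coef(fit),
         se = ct[, "Std. Error"],
         t_values = ct[, "t value"],
         p_values = ct[, "Pr(>|t|)"],
         standardized_coefficients = std_coef,
         vif = vif,
         bic = n * log(rss / n) + (k + 1) * log(n),
         r_squared = sm$r.squared,
         fitted = annual_series(design$years, stats::fitted(fit),
                                units = design$units),
         residuals = annual_series(design$years, stats::residuals(fit),
                                   units = design$units),
         n = n,
         n_skipped = n_skipped,
         design = design,
         lm_fit = fit),
    class = "attribution_model")
}

#' @export
print.attribution_model <- function(x, ...) {
  cat(sprintf("<attribution_model> %d years, %d terms + intercept, R2 = %.3f, BIC = %.2f\n",
              x$n, length(x$selected_terms), x$r_squared, x$bic))
  print(model_table(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Coefficient table of a fitted attribution model
#'
#' One row per term (intercept first): estimate, standard error, t, p,
#' standardized coefficient, and VIF — the shape used to report the load
#' regression.
#'
#' @param model An `attribution_model` from [best_subset_bic()].
#' @return A data frame.
#' @export
model_table <- function(model) {
  stopifnot(inherits(model, "attribution_model"))
  terms <- names(model$coefficients)
  data.frame(
    term = terms,
    estimate = unname(model$coefficients),
    se = unname(model$se),
    t_value = unname(model$t_values),
    p_value = unname(model$p_values),
    std_coef = c(NA_real_, unname(model$standardized_coefficients))[
      seq_along(terms)],
    vif = c(NA_real_, unname(model$vif))[seq_along(terms)]
  )
}
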
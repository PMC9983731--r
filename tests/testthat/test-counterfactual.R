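# small deterministic fit shared across scenario tests
fit_toy_model <- function(seed = 44, lags = c(2, 9), degree = 2) {
  set.seed(seed)
  bal <- annual_series(1950:2017, 1000 + 10 * (1950:2017 - 1950) +
                         rnorm(68, 0, 150))
  yrs <- 1975:2017
  load <- annual_series(yrs, 50 + 0.3 * series_value(bal, yrs - 2) +
                          0.2 * series_value(bal, yrs - 9) +
                          2 * (yrs - 1975) + rnorm(43, 0, 20))
  des <- build_design(load, bal, candidate_lags = lags,
                      max_year_degree = degree, year_index_origin = 1975)
  list(bal = bal, des = des, model = best_subset_bic(des))
}

test_that("scenario designs freeze the right columns at the right values", {
  tm <- fit_toy_model()
  dA <- scenario_design(tm$des, tm$model, "A")
  # each selected lag-k column pinned to its 1975 value = balance(1975 - k)
  for (cc in grep("^lag", tm$model$selected_terms, value = TRUE)) {
    k <- as.integer(sub("lag", "", cc))
    expect_equal(unname(dA$X[, cc]),
                 rep(series_value(tm$bal, 1975 - k), length(dA$years)))
    # spot check per the indexing contract: value at 2000 is balance(1975-k)
    expect_equal(dA$X["2000", cc], series_value(tm$bal, 1975 - k))
  }
  # year columns untouched in A
  for (cc in grep("^year", colnames(dA$X), value = TRUE)) {
    expect_equal(dA$X[, cc], tm$des$X[, cc])
  }

  dB <- scenario_design(tm$des, tm$model, "B")
  for (cc in grep("^year", tm$model$selected_terms, value = TRUE)) {
    expect_equal(unname(dB$X[, cc]), rep(dB$X["1975", cc], length(dB$years)))
  }
  for (cc in grep("^lag", colnames(dB$X), value = TRUE)) {
    expect_equal(dB$X[, cc], tm$des$X[, cc])
  }

  # common-freeze alternative: all lag columns take balance(1975)
  dC <- scenario_design(tm$des, tm$model, "A", freeze_mode = "common",
                        balance = tm$bal)
  for (cc in grep("^lag", tm$model$selected_terms, value = TRUE)) {
    expect_equal(unname(dC$X[, cc]),
                 rep(series_value(tm$bal, 1975), length(dC$years)))
  }
  expect_error(scenario_design(tm$des, tm$model, "A",
                               freeze_mode = "common"), "balance")
  expect_error(scenario_design(tm$des, tm$model, "A", freeze_year = 1900),
               "not a prediction year")
})

test_that("scenarios are no-ops when the model lacks the frozen terms", {
  # model with no year terms: scenario B changes nothing
  tm <- fit_toy_model(seed = 45, degree = 0)
  expect_false(any(grepl("^year", tm$model$selected_terms)))
  dB <- scenario_design(tm$des, tm$model, "B")
  expect_identical(dB$X, tm$des$X)

  # model with no lag terms: scenario A changes nothing
  set.seed(46)
  bal <- annual_series(1950:2017, rnorm(68, 1000, 100))
  yrs <- 1975:2017
  load <- annual_series(yrs, 10 + 5 * (yrs - 1975) + rnorm(43, 0, 5))
  des <- build_design(load, bal, candidate_lags = c(0, 3),
                      max_year_degree = 2)
  m <- best_subset_bic(des)
  expect_false(any(grepl("^lag", m$selected_terms)))
  dA <- scenario_design(des, m, "A")
  expect_identical(dA$X, des$X)
})

test_that("prediction reproduces OLS fitted values and hand arithmetic", {
  tm <- fit_toy_model()
  expect_equal(predict(tm$model)$value, tm$model$fitted$value)

  # hand-built two-term model on three years
  X <- cbind(lag1 = c(10, 20, 30), year1 = c(0, 1, 2))
  rownames(X) <- 2000:2002
  des <- structure(list(years = 2000:2002, response = c(0, 0, 0), X = X,
                        year_index_origin = 2000, candidate_lags = 1L,
                        max_year_degree = 1, units = "kg km-2 yr-1"),
                   class = "lag_design")
  hand <- structure(
    list(selected_terms = c("lag1", "year1"),
         coefficients = c("(Intercept)" = 2, lag1 = 0.5, year1 = -1)),
    class = "attribution_model")
  expect_equal(predict(hand, des)$value,
               c(2 + 5, 2 + 10 - 1, 2 + 15 - 2))

  # zeroed design returns the intercept everywhere
  des0 <- des
  des0$X[] <- 0
  expect_equal(predict(hand, des0)$value, rep(2, 3))

  bad <- des
  colnames(bad$X) <- c("lag2", "year1")
  expect_error(predict(hand, bad), "lacks selected terms")
})

test_that("impact summaries compare window means", {
  a <- annual_series(2010:2017, rep(440, 8))
  b <- annual_series(2010:2017, rep(220, 8))
  imp <- impact_summary(a, b, window = c(2013, 2017), scenario = "A")
  expect_equal(imp$original_mean, 440)
  expect_equal(imp$counterfactual_mean, 220)
  expect_equal(imp$delta_percent, -50)
  same <- impact_summary(a, a, window = c(2013, 2017))
  expect_equal(same$delta, 0)
  expect_equal(same$delta_percent, 0)
  expect_error(impact_summary(a, b, window = c(2016, 2020)), "covered")
})

test_that("counterfactual identities hold on noise-free synthetic truth", {
  # no latent year term in truth => scenario B equals the original
  comp <- generate_components(default_component_config("N"), seed = 9)
  bal <- compute_balance(comp, quiet = TRUE)
  tr <- synthetic_truth(lag_coefficients = c("2" = 0.25, "9" = 0.35),
                        year_poly_coefficients = numeric(0),
                        intercept = 100, noise_sd = 0)
  load <- generate_loads(bal, tr, 1975:2017)
  des <- build_design(load, bal, candidate_lags = c(2, 9),
                      max_year_degree = 2, year_index_origin = 1975)
  m <- suppressWarnings(best_subset_bic(des))
  cf <- run_counterfactuals(m, des)
  expect_equal(cf$B$predictions$value, cf$original$value, tolerance = 1e-6)
  expect_equal(cf$B$impact$delta_percent, 0, tolerance = 1e-6)

  # constant balances => scenario A equals the original
  balc <- annual_series(1950:2017, rep(1500, 68))
  yrs <- 1975:2017
  loadc <- annual_series(yrs, 100 + 0.2 * series_value(balc, yrs - 2) +
                           3 * (yrs - 1975))
  desc <- build_design(loadc, balc, candidate_lags = c(2, 9),
                       max_year_degree = 2, year_index_origin = 1975)
  mc <- suppressWarnings(best_subset_bic(desc))
  cfc <- run_counterfactuals(mc, desc)
  expect_equal(cfc$A$predictions$value, cfc$original$value,
               tolerance = 1e-8)
})
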
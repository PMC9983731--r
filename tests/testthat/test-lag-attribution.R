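test_that("AR(1) pre-whitening estimates phi consistently", {
  set.seed(31)
  # long AR(1) with phi = 0.7: Yule-Walker estimate should be close
  n <- 1000
  x <- as.numeric(arima.sim(list(ar = 0.7), n))
  pw <- prewhiten_ar1(annual_series(seq_len(n) + 1000, x))
  expect_gt(pw$phi, 0.65)
  expect_lt(pw$phi, 0.75)
  expect_length(pw$residuals$value, n - 1)
  # whitening reduces the lag-1 autocorrelation
  ac <- function(v) cor(v[-1], v[-length(v)])
  expect_lt(abs(ac(pw$residuals$value)), abs(ac(x)))

  # white noise in, phi near zero on average
  phis <- vapply(1:200, function(i) {
    set.seed(1000 + i)
    prewhiten_ar1(annual_series(1951:2000, rnorm(50)))$phi
  }, numeric(1))
  expect_lt(abs(mean(phis)), 0.03 + 2 / sqrt(50 * 200))

  expect_error(prewhiten_ar1(annual_series(1951:2000, rep(1, 50))),
               "constant")
  expect_error(prewhiten_ar1(annual_series(1991:1995, rnorm(5))),
               "at least 10")
})

test_that("the lag screen finds a planted lag and honors its modes", {
  set.seed(32)
  bal <- annual_series(1950:2017, rnorm(68, 1000, 200))
  load_r <- annual_series(1976:2017,
                          0.5 * series_value(bal, 1976:2017 - 3) +
                            rnorm(42, 0, 30))
  sc <- lag_correlation_screen(load_r, bal, max_lag = 10,
                               mode = "positive_and_significant")
  expect_true(3 %in% sc)
  tab <- attr(sc, "screen")
  expect_equal(tab$lag, 0:10)
  expect_true(all(tab$p[tab$lag %in% sc] < 0.05))

  # positive_only admits any positive correlation however weak
  sc2 <- lag_correlation_screen(load_r, bal, max_lag = 10,
                                mode = "positive_only")
  weak <- tab$r > 0 & tab$p > 0.05
  expect_true(all(tab$lag[weak] %in% sc2))
  expect_true(all(sc %in% sc2))

  expect_error(lag_correlation_screen(load_r, bal, max_lag = 30), "0..25")
})

test_that("the design matrix aligns lags and indexed-year polynomials", {
  bal <- compute_balance(generate_components(default_component_config("N"),
                                             seed = 4), quiet = TRUE)
  load <- annual_series(1975:2017, rnorm(43, 500, 50))
  des <- build_design(load, bal, candidate_lags = c(2, 4, 9, 11),
                      max_year_degree = 2, year_index_origin = 1975)
  expect_equal(length(des$years), 43)
  expect_equal(colnames(des$X),
               c("lag2", "lag4", "lag9", "lag11", "year1", "year2"))
  expect_equal(des$X[, "year1"], setNames(0:42, 1975:2017))
  expect_equal(des$X[, "year2"], setNames((0:42)^2, 1975:2017))
  # spot-check lag columns against direct indexing
  set.seed(5)
  for (i in 1:10) {
    y <- sample(des$years, 1)
    k <- sample(c(2, 4, 9, 11), 1)
    expect_equal(des$X[as.character(y), paste0("lag", k)],
                 bal$value[match(y - k, bal$year)])
  }
  # lag 0 is the contemporaneous balance
  des0 <- build_design(load, bal, candidate_lags = 0, max_year_degree = 0)
  expect_equal(unname(des0$X[, "lag0"]), series_value(bal, 1975:2017))
  # rows with incomplete lag coverage are trimmed
  shortbal <- series_window(bal, 1970, 2017)
  des2 <- build_design(load, shortbal, candidate_lags = 9,
                       max_year_degree = 1)
  expect_equal(min(des2$years), 1979)
  expect_error(build_design(load, bal, integer(0), 0), "empty design")
})

test_that("best-subset selection recovers planted structure", {
  set.seed(34)
  bal <- annual_series(1950:2017, rnorm(68, 1000, 250))
  yrs <- 1975:2017
  # strong single-lag signal
  load <- annual_series(yrs, 5 + 0.4 * series_value(bal, yrs - 2) +
                          rnorm(43, 0, 10))
  des <- build_design(load, bal, candidate_lags = c(0, 2, 5, 8),
                      max_year_degree = 2)
  m <- best_subset_bic(des)
  expect_identical(m$selected_terms, "lag2")
  expect_equal(unname(m$coefficients["lag2"]), 0.4, tolerance = 0.05)

  # pure quadratic in tau selects {year1, year2} under hierarchy
  load2 <- annual_series(yrs, 100 + 3 * (yrs - 1975) + 0.5 * (yrs - 1975)^2 +
                           rnorm(43, 0, 5))
  des2 <- build_design(load2, bal, candidate_lags = c(0, 2, 5, 8),
                       max_year_degree = 3)
  m2 <- best_subset_bic(des2, enforce_year_hierarchy = TRUE)
  expect_identical(m2$selected_terms, c("year1", "year2"))
})

test_that("the selector agrees with an independent QR-based enumerator", {
  for (seed in 1:12) {
    n_year <- seed %% 4  # 0..3 year columns
    p <- sample(4:12, 1)
    des <- random_design(p, n = 40, n_year = n_year, seed = 200 + seed)
    m <- best_subset_bic(des, max_terms = 8)
    ora <- oracle_best_subset(des$X, des$response, max_terms = 8)
    expect_identical(sort(m$selected_terms), sort(ora$terms))
    expect_equal(m$bic, ora$bic, tolerance = 1e-8)
  }
})

test_that("model diagnostics behave like OLS diagnostics should", {
  des <- random_design(6, n = 50, n_year = 2, seed = 77)
  m <- best_subset_bic(des, max_terms = 6)
  k <- length(m$selected_terms)
  expect_equal(length(m$coefficients), k + 1)
  expect_equal(mean(m$residuals$value), 0, tolerance = 1e-10)
  expect_true(all(m$vif >= 1 - 1e-12))
  expect_true(m$r_squared >= 0 && m$r_squared <= 1)
  # p-values match the two-sided t distribution with n-k-1 df
  expect_equal(unname(m$p_values[-1]),
               unname(2 * pt(-abs(m$t_values[-1]), df = m$n - k - 1)))

  # standardized coefficients are invariant to affine rescaling
  des2 <- des
  des2$X[, m$selected_terms[1]] <- 10 * des2$X[, m$selected_terms[1]] + 3
  m2 <- best_subset_bic(des2, max_terms = 6)
  expect_identical(m2$selected_terms, m$selected_terms)
  expect_equal(m2$standardized_coefficients, m$standardized_coefficients,
               tolerance = 1e-8)

  # VIF is exactly 1 for orthogonal regressors
  Xo <- qr.Q(qr(matrix(rnorm(40 * 3), 40, 3)))
  colnames(Xo) <- paste0("lag", 0:2)
  rownames(Xo) <- 1975:2014
  deso <- structure(list(years = 1975:2014,
                         response = as.numeric(Xo %*% c(1, 2, 3)) +
                           rnorm(40, 0, 0.1),
                         X = Xo, year_index_origin = 1975,
                         candidate_lags = 0:2, max_year_degree = 0,
                         units = "kg km-2 yr-1"),
                    class = "lag_design")
  mo <- best_subset_bic(deso, max_terms = 3)
  # orthogonality in the raw columns is preserved enough after centering
  expect_true(all(abs(mo$vif - 1) < 0.1))
})
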
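# Independent reference implementations used to cross-check the package.
# These deliberately use different code paths (double loops, lm/QR fits)
# than the functions they validate.

# all-pairs-median slope/intercept by explicit double loop
oracle_theil_sen <- function(year, value) {
  n <- length(year)
  slopes <- c()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      slopes <- c(slopes, (value[j] - value[i]) / (year[j] - year[i]))
    }
  }
  slope <- median(slopes)
  list(slope = slope, intercept = median(value - slope * year))
}

# exhaustive best-subset by QR least squares (stats::lm.fit), recursing over
# subset sizes with utils::combn; same BIC formula, same tie convention
oracle_best_subset <- function(X, y, max_terms = 8, hierarchy = TRUE) {
  n <- length(y)
  p <- ncol(X)
  cn <- colnames(X)
  hier_ok <- function(tms) {
    !(("year3" %in% tms && !"year2" %in% tms) ||
        ("year2" %in% tms && !"year1" %in% tms))
  }
  bic_of <- function(idx) {
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X[, idx, drop = FALSE]), y)
    if (fit$rank < length(idx) + 1) return(NA_real_)
    rss <- sum(fit$residuals^2)
    n * log(rss / n) + (length(idx) + 1) * log(n)
  }
  best_bic <- bic_of(integer(0))
  best_terms <- character(0)
  for (k in seq_len(min(max_terms, p, n - 2))) {
    sets <- utils::combn(p, k)
    for (j in seq_len(ncol(sets))) {
      idx <- sets[, j]
      if (hierarchy && !hier_ok(cn[idx])) next
      b <- bic_of(idx)
      if (!is.na(b) && b < best_bic - 1e-9) {
        best_bic <- b
        best_terms <- cn[idx]
      }
    }
  }
  list(terms = best_terms, bic = best_bic)
}

# small random lag_design-like object for selector cross-checks
random_design <- function(p, n = 40, n_year = 0, seed = 1) {
  set.seed(seed)
  n_lag <- p - n_year
  X <- matrix(rnorm(n * n_lag, mean = 5), n, n_lag)
  # induce some collinearity between neighbouring columns
  if (n_lag > 1) {
    for (j in 2:n_lag) X[, j] <- 0.6 * X[, j - 1] + 0.4 * X[, j]
  }
  cn <- paste0("lag", seq_len(n_lag) - 1)
  if (n_year > 0) {
    tau <- seq_len(n) - 10
    for (d in seq_len(n_year)) X <- cbind(X, tau^d)
    cn <- c(cn, paste0("year", seq_len(n_year)))
  }
  colnames(X) <- cn
  years <- seq(1975, length.out = n)
  rownames(X) <- years
  k_true <- sample(p, min(3, p))
  beta <- rnorm(length(k_true), 0, 1.5)
  y <- 2 + X[, k_true, drop = FALSE] %*% beta + rnorm(n, 0, 2)
  structure(list(years = years, response = as.numeric(y), X = X,
                 year_index_origin = 1975, candidate_lags = integer(0),
                 max_year_degree = n_year, units = "kg km-2 yr-1"),
            class = "lag_design")
}

# standard N-truth synthetic instance used by recovery-style tests
make_synthetic_instance <- function(seed_comp, seed_load, target_r2 = 0.8,
                                    nutrient = "N") {
  comp <- generate_components(default_component_config(nutrient),
                              seed = seed_comp)
  bal <- compute_balance(comp, quiet = TRUE)
  tr <- synthetic_truth(seed = seed_load)
  tr$noise_sd <- calibrate_noise_sd(bal, tr, 1975:2017,
                                    target_r2 = target_r2)
  load <- generate_loads(bal, tr, 1975:2017)
  list(components = comp, balance = bal, truth = tr, load = load)
}
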
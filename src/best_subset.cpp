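#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Exhaustive best-subset search minimising BIC = n*ln(RSS/n) + (k+1)*ln(n)
// over OLS fits with an intercept.
//
// The intercept is absorbed by centering y and the columns of X, so each
// subset costs one small in-place Cholesky solve of the centered Gram
// submatrix (fixed-size stack buffers, no allocation); centering also keeps
// the normal equations well conditioned when columns differ wildly in
// scale. Subsets are enumerated in increasing size and, within a size, in
// lexicographic column order; a candidate replaces the incumbent only when
// its BIC is smaller by more than `tol`, which realises the tie-break
// "fewer terms, then lexicographically earlier". `hier_parent` (0-based,
// -1 for none) marks columns admissible only together with a parent column
// (polynomial hierarchy). Numerically rank-deficient subsets are skipped
// and counted.
//
// Returns: list(terms = 1-based column indices, bic, n_skipped).

static const int MAXK = 32;

// Cholesky solve of (m x m) SPD system in place; returns false if not PD
// relative to the original diagonal.
static bool chol_solve(double* A, const double* diag0, double* b, int m) {
  for (int j = 0; j < m; ++j) {
    double d = A[j * m + j];
    for (int k = 0; k < j; ++k) d -= A[j * m + k] * A[j * m + k];
    if (d <= 1e-10 * diag0[j]) return false;
    d = std::sqrt(d);
    A[j * m + j] = d;
    for (int i = j + 1; i < m; ++i) {
      double s = A[i * m + j];
      for (int k = 0; k < j; ++k) s -= A[i * m + k] * A[j * m + k];
      A[i * m + j] = s / d;
    }
  }
  for (int i = 0; i < m; ++i) {
    double s = b[i];
    for (int k = 0; k < i; ++k) s -= A[i * m + k] * b[k];
    b[i] = s / A[i * m + i];
  }
  for (int i = m - 1; i >= 0; --i) {
    double s = b[i];
    for (int k = i + 1; k < m; ++k) s -= A[k * m + i] * b[k];
    b[i] = s / A[i * m + i];
  }
  return true;
}

// [[Rcpp::export(name = ".best_subset_search")]]
List best_subset_search(const arma::mat& X, const arma::vec& y,
                        int max_terms, IntegerVector hier_parent,
                        double tol = 1e-9) {
  const int n = X.n_rows;
  const int p = X.n_cols;
  if (max_terms >= MAXK) stop("max_terms too large");

  arma::mat Xc = X;
  for (int j = 0; j < p; ++j) Xc.col(j) -= arma::mean(Xc.col(j));
  arma::vec yc = y - arma::mean(y);

  const arma::mat G = Xc.t() * Xc;     // p x p, column-major
  const arma::vec g = Xc.t() * yc;
  const double yty = arma::dot(yc, yc);
  const double logn = std::log((double)n);
  const double* Gp = G.memptr();

  double best_bic = R_PosInf;
  std::vector<int> best_idx;
  long n_skipped = 0;

  {
    double rss = yty < 1e-300 ? 1e-300 : yty;
    best_bic = n * std::log(rss / n) + logn;  // intercept-only
  }

  int comb[MAXK];
  double Gs[MAXK * MAXK];
  double gs[MAXK];
  double gs0[MAXK];
  double d0[MAXK];

  for (int k = 1; k <= max_terms && k <= p; ++k) {
    for (int i = 0; i < k; ++i) comb[i] = i;
    while (true) {
      bool ok = true;
      for (int i = 0; i < k && ok; ++i) {
        int par = hier_parent[comb[i]];
        if (par >= 0) {
          bool found = false;
          for (int j = 0; j < k; ++j) if (comb[j] == par) { found = true; break; }
          if (!found) ok = false;
        }
      }
      if (ok) {
        for (int j = 0; j < k; ++j) {
          const double* col = Gp + (size_t)comb[j] * p;
          for (int i = 0; i < k; ++i) Gs[j * k + i] = col[comb[i]];
          gs[j] = gs0[j] = g(comb[j]);
          d0[j] = col[comb[j]];
        }
        if (!chol_solve(Gs, d0, gs, k)) {
          ++n_skipped;
        } else {
          double fit = 0.0;
          for (int i = 0; i < k; ++i) fit += gs[i] * gs0[i];
          double rss = yty - fit;
          if (rss < 1e-300) rss = 1e-300;
          double bic = n * std::log(rss / n) + (k + 1) * logn;
          if (bic < best_bic - tol) {
            best_bic = bic;
            best_idx.assign(comb, comb + k);
          }
        }
      }
      int i = k - 1;
      while (i >= 0 && comb[i] == p - k + i) --i;
      if (i < 0) break;
      ++comb[i];
      for (int j = i + 1; j < k; ++j) comb[j] = comb[j - 1] + 1;
    }
  }

  IntegerVector terms(best_idx.size());
  for (size_t i = 0; i < best_idx.size(); ++i) terms[i] = best_idx[i] + 1;
  return List::create(_["terms"] = terms,
                      _["bic"] = best_bic,
                      _["n_skipped"] = (double)n_skipped);
}
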
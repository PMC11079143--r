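// Sample-recursive adaptive noise cancellers (NLMS, RLS).
//
// All EEG channels share the same acceleration reference, so the reference
// statistics (RLS inverse correlation matrix, NLMS reference energy) are
// computed once per sample and the per-channel work is O(L). This is an
// exact restructuring of per-channel filtering, not an approximation.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Lagged reference window at sample n (0-based): xw[k] = x[n-k], k = 0..L-1,
// zero-padded before the start of the recording.
static inline void fill_window(const arma::vec& x, int n, arma::vec& xw) {
  const int L = xw.n_elem;
  for (int k = 0; k < L; ++k)
    xw[k] = (n - k >= 0) ? x[n - k] : 0.0;
}

// [[Rcpp::export(name = ".nlms_filter_multi")]]
List nlms_filter_multi(const arma::mat& d, const arma::vec& x, int L,
                       double mu, double eps, const arma::mat& w0) {
  const int n = d.n_rows, C = d.n_cols;
  arma::mat W = w0;                    // L x C
  arma::mat e(n, C), y(n, C);
  arma::vec xw(L, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    fill_window(x, i, xw);
    double energy = arma::dot(xw, xw);
    arma::rowvec yi = xw.t() * W;      // 1 x C
    arma::rowvec ei = d.row(i) - yi;
    y.row(i) = yi;
    e.row(i) = ei;
    W += (mu / (eps + energy)) * (xw * ei);
  }
  return List::create(_["e"] = e, _["y"] = y, _["W"] = W);
}

// [[Rcpp::export(name = ".rls_filter_multi")]]
List rls_filter_multi(const arma::mat& d, const arma::vec& x, int L,
                      double forget, double delta, const arma::mat& w0) {
  const int n = d.n_rows, C = d.n_cols;
  arma::mat W = w0;                    // L x C
  arma::mat P = delta * arma::eye<arma::mat>(L, L);
  arma::mat e(n, C), y(n, C);
  arma::vec xw(L, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    fill_window(x, i, xw);
    arma::vec Px = P * xw;
    double denom = forget + arma::dot(xw, Px);
    arma::vec k = Px / denom;
    arma::rowvec yi = xw.t() * W;
    arma::rowvec ei = d.row(i) - yi;
    y.row(i) = yi;
    e.row(i) = ei;
    W += k * ei;
    // P is symmetric; x'P == (Px)' so one mat-vec suffices
    P -= k * Px.t();
    P /= forget;
    if (i % 1000 == 999) {
      P = 0.5 * (P + P.t());           // counter drift from rank-1 updates
      if (!P.is_finite())
        stop("RLS diverged: inverse-correlation matrix is not finite at sample %d", i + 1);
    }
  }
  if (!P.is_finite() || !W.is_finite())
    stop("RLS diverged: non-finite state at end of run");
  return List::create(_["e"] = e, _["y"] = y, _["W"] = W);
}
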
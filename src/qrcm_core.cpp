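// Hot numerical kernels for the integrated-loss estimator: the quadrature
// pinball loss with its (almost-everywhere) gradient, and the first upward
// crossing of the fitted quantile curves used by the PIT and the curvature
// matrix. Everything else stays in R.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Integrated pinball loss over Gauss-Legendre nodes and its gradient with
// respect to the full theta matrix.
//   X: n x m design; theta: m x k; B: K x k basis at the nodes;
//   pnod, wnod: node positions and weights; yw: working response.
// loss = sum_k w_k sum_i rho_{p_k}(yw_i - eta_ik), eta = (X theta) B'.
// grad = X' (Omega W B) - colSums(X) (x) (w*p)' B, Omega_ik = 1(yw_i <= eta_ik).
// [[Rcpp::export]]
Rcpp::List cqr_loss_grad(const arma::mat& X, const arma::mat& theta,
                         const arma::mat& B, const arma::vec& pnod,
                         const arma::vec& wnod, const arma::vec& yw,
                         const bool want_grad, const bool want_eta) {
  const uword n = X.n_rows, K = pnod.n_elem;
  mat eta = (X * theta) * B.t();            // n x K
  double loss = 0.0;
  mat omega;
  if (want_grad) omega.zeros(n, K);
  for (uword k = 0; k < K; ++k) {
    const double p = pnod(k), w = wnod(k);
    const double* e = eta.colptr(k);
    double acc_pos = 0.0, acc_neg = 0.0;
    if (want_grad) {
      double* o = omega.colptr(k);
      for (uword i = 0; i < n; ++i) {
        const double r = yw(i) - e[i];
        if (r > 0.0) acc_pos += r; else { acc_neg -= r; o[i] = 1.0; }
      }
    } else {
      for (uword i = 0; i < n; ++i) {
        const double r = yw(i) - e[i];
        if (r > 0.0) acc_pos += r; else acc_neg -= r;
      }
    }
    loss += w * (p * acc_pos + (1.0 - p) * acc_neg);
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("loss") = loss);
  if (want_grad) {
    mat WB = B.each_col() % wnod;            // K x k
    rowvec wpB = (wnod % pnod).t() * B;      // 1 x k
    mat G = X.t() * (omega * WB) - sum(X, 0).t() * wpB;
    out["grad_full"] = G;
  }
  if (want_eta) out["eta"] = eta;
  return out;
}

// First index-wise upward crossing of each fitted curve with the working
// response, linearly interpolated between adjacent nodes.
// Returns p_star (0 below range, 1 above range), the local slope
// d eta / d p at the crossing, and whether the crossing is interior.
// [[Rcpp::export]]
Rcpp::List cqr_first_crossing(const arma::mat& eta, const arma::vec& yw,
                              const arma::vec& pnod) {
  const uword n = eta.n_rows, K = pnod.n_elem;
  vec p_star(n), slope(n);
  slope.fill(datum::nan);
  Rcpp::LogicalVector interior(n);
  for (uword i = 0; i < n; ++i) {
    const double y = yw(i);
    if (eta(i, 0) >= y) { p_star(i) = (eta(i, 0) == y) ? pnod(0) : 0.0; continue; }
    uword k = 1;
    while (k < K && eta(i, k) < y) ++k;
    if (k == K) { p_star(i) = 1.0; continue; }
    const double e1 = eta(i, k - 1), e2 = eta(i, k);
    const double denom = e2 - e1;
    double frac = (std::abs(denom) > 1e-12) ? (y - e1) / denom : 0.0;
    if (frac < 0.0) frac = 0.0;
    if (frac > 1.0) frac = 1.0;
    p_star(i) = pnod(k - 1) + frac * (pnod(k) - pnod(k - 1));
    if (denom > 0.0) {
      slope(i) = denom / (pnod(k) - pnod(k - 1));
      interior(i) = true;
    }
  }
  return Rcpp::List::create(Rcpp::Named("p_star") = p_star,
                            Rcpp::Named("slope") = slope,
                            Rcpp::Named("interior") = interior);
}
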
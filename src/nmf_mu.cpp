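#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lee-Seung multiplicative updates for min ||X - W H||_F^2 with W,H >= 0.
// Stops when the relative change of the Frobenius error drops below tol.
// Returns W, H, the final relative error and the per-iteration error trace
// (so callers can assert monotone descent).
// [[Rcpp::export]]
Rcpp::List nmf_mu_cpp(const arma::mat& X, arma::mat W, arma::mat H,
                      int max_iter, double tol) {
  const double eps = 1e-12;
  const double normX = norm(X, "fro");
  std::vector<double> errs;
  errs.reserve(max_iter);
  double prev = datum::inf;
  for (int it = 0; it < max_iter; ++it) {
    // H update
    mat WtX = W.t() * X;
    mat WtWH = W.t() * W * H + eps;
    H %= WtX / WtWH;
    // W update
    mat XHt = X * H.t();
    mat WHHt = W * (H * H.t()) + eps;
    W %= XHt / WHHt;
    double err = norm(X - W * H, "fro") / (normX + eps);
    errs.push_back(err);
    if (std::abs(prev - err) < tol) break;
    prev = err;
  }
  return Rcpp::List::create(Rcpp::Named("W") = W,
                            Rcpp::Named("H") = H,
                            Rcpp::Named("rel_err") = errs.back(),
                            Rcpp::Named("err_trace") = errs);
}
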
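#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Lee-Seung multiplicative updates for the Frobenius loss ||M - WH||_F^2.
// A small epsilon guards the denominators; the loss is recorded after every
// full (H then W) update so monotonicity can be asserted from R.
// [[Rcpp::export]]
Rcpp::List nmf_mu_cpp(const arma::mat& M, arma::mat W, arma::mat H,
                      const int max_iter, const double tol) {
  const double eps = 1e-12;
  std::vector<double> loss;
  loss.reserve(static_cast<size_t>(max_iter) + 1);
  double prev = accu(square(M - W * H));
  loss.push_back(prev);
  bool converged = false;
  int it = 0;
  while (it < max_iter) {
    ++it;
    H %= (W.t() * M) / (W.t() * W * H + eps);
    W %= (M * H.t()) / (W * H * H.t() + eps);
    const double cur = accu(square(M - W * H));
    loss.push_back(cur);
    if (std::fabs(prev - cur) <= tol * std::max(prev, eps)) {
      converged = true;
      break;
    }
    prev = cur;
  }
  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("H") = H,
      Rcpp::Named("loss") = loss, Rcpp::Named("n_iter") = it,
      Rcpp::Named("converged") = converged);
}

// Fixed-W nonnegative projection: only H is updated. Used for the optional
// "project" mode of per-cycle pattern extraction.
// [[Rcpp::export]]
Rcpp::List nmf_project_cpp(const arma::mat& M, const arma::mat& W, arma::mat H,
                           const int max_iter, const double tol) {
  const double eps = 1e-12;
  const mat WtW = W.t() * W;
  const mat WtM = W.t() * M;
  double prev = accu(square(M - W * H));
  bool converged = false;
  int it = 0;
  while (it < max_iter) {
    ++it;
    H %= WtM / (WtW * H + eps);
    const double cur = accu(square(M - W * H));
    if (std::fabs(prev - cur) <= tol * std::max(prev, eps)) {
      converged = true;
      break;
    }
    prev = cur;
  }
  return Rcpp::List::create(Rcpp::Named("H") = H, Rcpp::Named("n_iter") = it,
                            Rcpp::Named("converged") = converged);
}
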
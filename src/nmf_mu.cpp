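#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multiplicative-update NMF minimising the squared Frobenius
// reconstruction error ||X - W H||_F^2 (Lee & Seung updates).
// Updates are non-increasing in the objective up to the epsilon guard.
// Returns the factors and the per-iteration objective trace so callers
// can assert monotonicity and convergence behaviour.
// [[Rcpp::export]]
Rcpp::List nmf_mu_cpp(const arma::mat& X, arma::mat W, arma::mat H,
                      const int max_iter, const double tol) {
  const double eps = 1e-12;
  // absolute floor: an essentially exact factorisation counts as converged
  const double floor_obj = 1e-12 * accu(square(X));
  std::vector<double> trace;
  trace.reserve(64);
  double prev = accu(square(X - W * H));
  trace.push_back(prev);
  bool converged = false;
  int iter = 0;
  for (iter = 1; iter <= max_iter; ++iter) {
    // H update: H <- H .* (W'X) ./ (W'W H)
    H %= (W.t() * X) / (W.t() * W * H + eps);
    // W update: W <- W .* (X H') ./ (W H H')
    W %= (X * H.t()) / (W * (H * H.t()) + eps);
    const double obj = accu(square(X - W * H));
    trace.push_back(obj);
    if (std::fabs(prev - obj) <= tol * std::max(prev, eps) ||
        obj <= floor_obj) {
      converged = true;
      break;
    }
    prev = obj;
  }
  return Rcpp::List::create(
      Rcpp::Named("W") = W, Rcpp::Named("H") = H,
      Rcpp::Named("objective") = trace.back(),
      Rcpp::Named("trace") = trace,
      Rcpp::Named("iterations") = std::min(iter, max_iter),
      Rcpp::Named("converged") = converged);
}

// Fit H against a fixed basis W (multiplicative H updates only).
// Used when projecting new or permuted data onto an existing model.
// [[Rcpp::export]]
Rcpp::List nmf_project_cpp(const arma::mat& X, const arma::mat& W,
                           arma::mat H, const int max_iter,
                           const double tol) {
  const double eps = 1e-12;
  double prev = accu(square(X - W * H));
  bool converged = false;
  for (int iter = 1; iter <= max_iter; ++iter) {
    H %= (W.t() * X) / (W.t() * W * H + eps);
    const double obj = accu(square(X - W * H));
    if (std::fabs(prev - obj) <= tol * std::max(prev, eps)) {
      converged = true;
      prev = obj;
      break;
    }
    prev = obj;
  }
  return Rcpp::List::create(Rcpp::Named("H") = H,
                            Rcpp::Named("objective") = prev,
                            Rcpp::Named("converged") = converged);
}
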
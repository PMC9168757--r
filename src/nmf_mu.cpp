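#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Multiplicative-update NMF for the Frobenius loss (Lee & Seung updates).
// W and H arrive pre-initialized (seeding happens on the R side so all
// randomness flows through R's RNG). Iteration stops when the relative loss
// change drops below tol or max_iter is reached.
// [[Rcpp::export]]
Rcpp::List nmf_mu_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol) {
  const double eps = 1e-12;
  const double vnorm = arma::norm(V, "fro");
  std::vector<double> losses;
  losses.reserve(64);
  double prev = -1.0;
  for (int it = 0; it < max_iter; ++it) {
    H %= (W.t() * V) / (W.t() * W * H + eps);
    W %= (V * H.t()) / (W * H * H.t() + eps);
    const double loss = arma::norm(V - W * H, "fro");
    losses.push_back(loss);
    if (prev >= 0.0 && std::abs(prev - loss) < tol * std::max(prev, eps)) {
      break;
    }
    prev = loss;
  }
  return Rcpp::List::create(
      Rcpp::Named("W") = W,
      Rcpp::Named("H") = H,
      Rcpp::Named("rel_error") = losses.back() / std::max(vnorm, eps),
      Rcpp::Named("loss") = losses,
      Rcpp::Named("n_iter") = static_cast<int>(losses.size()));
}
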
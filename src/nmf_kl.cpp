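#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Generalized KL divergence D(V || WH); zero entries of V contribute WH only.
static double kl_div(const arma::mat& V, const arma::mat& WH) {
  double s = 0.0;
  const double* v = V.memptr();
  const double* wh = WH.memptr();
  for (arma::uword i = 0; i < V.n_elem; ++i) {
    double w = wh[i] > 0 ? wh[i] : DBL_MIN;
    if (v[i] > 0) s += v[i] * std::log(v[i] / w) - v[i];
    s += w;
  }
  return s;
}

// Brunet multiplicative updates for KL-divergence NMF with the
// connectivity-stability stopping rule (check every check_interval
// iterations, stop after stop_stable consecutive unchanged checks).
// [[Rcpp::export(name = ".nmf_kl_cpp")]]
List nmf_kl_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                int max_iter, int check_interval, int stop_stable) {
  const double eps = std::numeric_limits<double>::epsilon();
  std::vector<double> trace;
  trace.push_back(kl_div(V, W * H));
  arma::uvec last_labels;
  int it = 0, stable = 0;
  arma::mat Q;
  while (it < max_iter) {
    int todo = std::min(check_interval, max_iter - it);
    for (int step = 0; step < todo; ++step) {
      Q = V / (W * H + eps);
      H %= (W.t() * Q);
      H.each_col() /= (arma::sum(W, 0).t() + eps);
      Q = V / (W * H + eps);
      W %= (Q * H.t());
      W.each_row() /= (arma::sum(H, 1).t() + eps);
      ++it;
    }
    trace.push_back(kl_div(V, W * H));
    arma::uvec labels = arma::index_max(H, 0).t();
    if (last_labels.n_elem && arma::all(labels == last_labels)) {
      if (++stable >= stop_stable) break;
    } else {
      stable = 0;
      last_labels = labels;
    }
  }
  return List::create(_["W"] = W, _["H"] = H,
                      _["divergence"] = NumericVector(trace.begin(), trace.end()),
                      _["iterations"] = it);
}
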
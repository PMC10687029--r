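#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exhaustive grid-search MLE for the Gaussian-CDF psychometric curve with
// lapse: p(r=1|s) = lambda/2 + (1-lambda) * Phi((s - mu)/sigma).
// For one condition's data, returns for every lambda the best (mu, sigma)
// pair and its log likelihood. mu values are visited in the order given
// (callers pass them sorted by |mu| for the deterministic tie-break:
// smallest sigma first, then smallest |mu|; ties resolved by strict
// improvement only).
// [[Rcpp::export]]
List psy_grid_scan(NumericVector s, IntegerVector r,
                   NumericVector mu, NumericVector sigma,
                   NumericVector lambda) {
  const int n = s.size(), nm = mu.size(), ns = sigma.size(), nl = lambda.size();
  NumericMatrix best_ll(nl, 1);
  IntegerVector best_mu(nl), best_sigma(nl);
  std::vector<double> ll(nl);
  std::vector<double> m(n);
  std::fill(best_ll.begin(), best_ll.end(), R_NegInf);
  for (int j = 0; j < ns; ++j) {
    const double inv = 1.0 / sigma[j];
    for (int i = 0; i < nm; ++i) {
      const double mui = mu[i];
      for (int k = 0; k < n; ++k) {
        // Phi((s - mu)/sigma) via erfc for tail accuracy
        const double z = (s[k] - mui) * inv;
        const double phi = 0.5 * erfc(-z * M_SQRT1_2);
        m[k] = r[k] == 1 ? phi : 1.0 - phi;
      }
      for (int l = 0; l < nl; ++l) {
        const double half_lam = 0.5 * lambda[l], one_m = 1.0 - lambda[l];
        double acc = 0.0;
        for (int k = 0; k < n; ++k) acc += std::log(half_lam + one_m * m[k]);
        ll[l] = acc;
      }
      for (int l = 0; l < nl; ++l) {
        if (ll[l] > best_ll(l, 0)) {
          best_ll(l, 0) = ll[l];
          best_mu[l] = i + 1;     // 1-based for R
          best_sigma[l] = j + 1;
        }
      }
    }
  }
  return List::create(_["logLik"] = best_ll(_, 0),
                      _["mu_index"] = best_mu,
                      _["sigma_index"] = best_sigma);
}
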
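#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// log(Phi(b) - Phi(a)) for b > a, standard normal, stable in both tails.
static double log_pnorm_diff_c(double a, double b) {
  if (a > 0) { double tmp = a; a = -b; b = -tmp; }  // mirror to lower tail
  const double la = R::pnorm(b, 0.0, 1.0, 1, 1);
  const double lb = R::pnorm(a, 0.0, 1.0, 1, 1);
  return la + log1p(-exp(lb - la));
}

// Decision variable d(x): log prior odds + category width term + log ratio
// of CDF differences.
static double d_logodds(double x, double sigma, double mu_l, double prior_term,
                        double s11, double s12, double s21, double s22) {
  const double ln = log_pnorm_diff_c((s11 - mu_l - x) / sigma,
                                     (s12 - mu_l - x) / sigma);
  const double ld = log_pnorm_diff_c((s21 - mu_l - x) / sigma,
                                     (s22 - mu_l - x) / sigma);
  return prior_term + ln - ld;
}

// Solve d(x) = target by bracket expansion + bisection (d is strictly
// increasing in x).
// [[Rcpp::export]]
double invert_d_cpp(double target, double sigma, double mu_l,
                    double prior_term, double s11, double s12,
                    double s21, double s22) {
  double lo = -1.0, hi = 1.0;
  while (d_logodds(lo, sigma, mu_l, prior_term, s11, s12, s21, s22) > target &&
         lo > -1e3) lo *= 2.0;
  while (d_logodds(hi, sigma, mu_l, prior_term, s11, s12, s21, s22) < target &&
         hi < 1e3) hi *= 2.0;
  for (int it = 0; it < 200; ++it) {
    const double mid = 0.5 * (lo + hi);
    if (hi - lo < 1e-10) break;
    if (d_logodds(mid, sigma, mu_l, prior_term, s11, s12, s21, s22) < target) {
      lo = mid;
    } else {
      hi = mid;
    }
  }
  return 0.5 * (lo + hi);
}

// Row-wise counts of Z[i, ] < thr[i].
// [[Rcpp::export]]
IntegerVector count_below_cpp(NumericMatrix Z, NumericVector thr) {
  const int n = Z.nrow(), m = Z.ncol();
  IntegerVector out(n);
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      if (Z(i, j) < thr[i]) ++out[i];
    }
  }
  return out;
}

// Counts of Zs[i, ] < thr(i, k) for each row i and threshold column k,
// where every row of Zs is sorted ascending (binary search per row).
// [[Rcpp::export]]
IntegerMatrix count_below_sorted_cpp(NumericMatrix Zs, NumericMatrix thr) {
  const int n = Zs.nrow(), m = Zs.ncol(), k = thr.ncol();
  IntegerMatrix out(n, k);
  const double *z = REAL(Zs);
  for (int i = 0; i < n; ++i) {
    for (int c = 0; c < k; ++c) {
      const double t = thr(i, c);
      int lo = 0, hi = m;                 // first j with Zs(i, j) >= t
      while (lo < hi) {
        const int mid = (lo + hi) / 2;
        if (z[i + (R_xlen_t)mid * n] < t) lo = mid + 1; else hi = mid;
      }
      out(i, c) = lo;
    }
  }
  return out;
}
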
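#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama simulation of a constant-drift Wiener process with
// symmetric absorbing bounds at +/-B, start nu0 = z*B, unit diffusion
// noise. Uses R's RNG so set.seed() governs reproducibility. Trials not
// absorbed within max_t (decision time) are censored.
// [[Rcpp::export]]
DataFrame simulate_ddm_cpp(NumericVector drift, double B, double z,
                           double t_nd, double dt, double max_t) {
  const int n = drift.size();
  const int max_steps = (int)std::ceil(max_t / dt);
  const double sq = std::sqrt(dt);
  IntegerVector choice(n);
  NumericVector rt(n);
  LogicalVector censored(n);
  RNGScope scope;
  for (int i = 0; i < n; ++i) {
    double nu = z * B;
    const double mu = drift[i];
    int step = 0;
    bool done = false;
    while (step < max_steps) {
      ++step;
      nu += mu * dt + sq * norm_rand();
      if (nu >= B) { choice[i] = 1; done = true; break; }
      if (nu <= -B) { choice[i] = -1; done = true; break; }
    }
    if (done) {
      rt[i] = step * dt + t_nd;
      censored[i] = false;
    } else {
      rt[i] = NA_REAL;
      choice[i] = NA_INTEGER;
      censored[i] = true;
    }
  }
  return DataFrame::create(_["choice"] = choice, _["rt"] = rt,
                           _["censored"] = censored);
}

// Crank-Nicolson propagation of the Fokker-Planck equation
//   dp/dt = -mu dp/dnu + 0.5 d^2p/dnu^2
// on [-B, B] with absorbing bounds, delta initial condition at z*B.
// Returns the first-passage density (per unit time) at each bound on the
// time grid t = dt, 2dt, ..., plus the surviving mass.
// [[Rcpp::export]]
List fp_first_passage_cpp(double drift, double B, double z,
                          double dnu, double dt, double t_max) {
  const double h = dnu, D = 0.5;
  const int M = (int)std::round(2.0 * B / h);     // intervals; nodes 0..M
  const int ni = M - 1;                           // interior nodes
  const int nt = (int)std::round(t_max / dt);
  if (ni < 3) stop("grid too coarse for the given bound");
  std::vector<double> p(ni, 0.0), pnew(ni), rhs(ni), cp(ni), dp(ni);
  // delta start split linearly between the two neighbouring nodes
  double pos = (z * B + B) / h;                   // in node units, 0..M
  int i0 = (int)std::floor(pos);
  double frac = pos - i0;
  if (i0 >= 1 && i0 <= ni) p[i0 - 1] += (1.0 - frac) / h;
  if (i0 + 1 >= 1 && i0 + 1 <= ni) p[i0] += frac / h;
  const double r = D * dt / (h * h);
  const double c = drift * dt / (4.0 * h);
  // A p_new = B p_old with A tridiag(-r/2 - c, 1 + r, -r/2 + c)
  //                       B tridiag( r/2 + c, 1 - r,  r/2 - c)
  const double a_sub = -0.5 * r - c, a_di = 1.0 + r, a_sup = -0.5 * r + c;
  const double b_sub = 0.5 * r + c, b_di = 1.0 - r, b_sup = 0.5 * r - c;
  NumericVector g_up(nt), g_low(nt);
  for (int t = 0; t < nt; ++t) {
    for (int i = 0; i < ni; ++i) {
      double v = b_di * p[i];
      if (i > 0) v += b_sub * p[i - 1];
      if (i < ni - 1) v += b_sup * p[i + 1];
      rhs[i] = v;
    }
    // Thomas algorithm
    cp[0] = a_sup / a_di;
    dp[0] = rhs[0] / a_di;
    for (int i = 1; i < ni; ++i) {
      const double m = a_di - a_sub * cp[i - 1];
      cp[i] = a_sup / m;
      dp[i] = (rhs[i] - a_sub * dp[i - 1]) / m;
    }
    pnew[ni - 1] = dp[ni - 1];
    for (int i = ni - 2; i >= 0; --i) pnew[i] = dp[i] - cp[i] * pnew[i + 1];
    std::swap(p, pnew);
    // one-sided second-order flux at the absorbing bounds
    g_low[t] = D * (4.0 * p[0] - p[1]) / (2.0 * h);
    g_up[t] = D * (4.0 * p[ni - 1] - p[ni - 2]) / (2.0 * h);
    if (g_low[t] < 0) g_low[t] = 0;
    if (g_up[t] < 0) g_up[t] = 0;
  }
  double mass = 0.0;
  for (int i = 0; i < ni; ++i) mass += p[i];
  mass *= h;
  NumericVector tgrid(nt);
  for (int t = 0; t < nt; ++t) tgrid[t] = (t + 1) * dt;
  return List::create(_["t"] = tgrid,
                      _["g_up"] = g_up, _["g_low"] = g_low,
                      _["survivor_mass"] = mass);
}
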
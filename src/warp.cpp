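#include <Rcpp.h>
using namespace Rcpp;

// Three-segment piecewise-linear time warp on the 101-point normalized grid.
// phi maps subject time -> reference time with knots (0,0), (t1,t1ref),
// (t2,t2ref), (1,1); the warped curve is subject(phi^{-1}(tau)) resampled by
// linear interpolation.

static inline double interp_curve(const double* v, int n, double x) {
  // linear interpolation of v (uniform grid on [0,1]) at x, clamped
  if (x <= 0.0) return v[0];
  if (x >= 1.0) return v[n - 1];
  double pos = x * (n - 1);
  int i = (int)pos;
  if (i >= n - 1) return v[n - 1];
  double frac = pos - i;
  return v[i] + frac * (v[i + 1] - v[i]);
}

static inline double phi_inv(double tau, double t1, double t2, double t1ref,
                             double t2ref) {
  // inverse warp: knots (0,0), (t1ref,t1), (t2ref,t2), (1,1)
  if (tau <= t1ref) return tau * t1 / t1ref;
  if (tau <= t2ref) return t1 + (tau - t1ref) * (t2 - t1) / (t2ref - t1ref);
  return t2 + (tau - t2ref) * (1.0 - t2) / (1.0 - t2ref);
}

static void warp_values(const double* sub, int n, double t1, double t2,
                        double t1ref, double t2ref, double* out) {
  double h = 1.0 / (n - 1);
  for (int i = 0; i < n; ++i)
    out[i] = interp_curve(sub, n, phi_inv(i * h, t1, t2, t1ref, t2ref));
}

static double deriv_cost(const double* warped, const double* dref, int n) {
  // Euclidean distance between first derivatives (central differences,
  // one-sided at endpoints) of the warped curve and the reference.
  double h = 1.0 / (n - 1);
  double ss = 0.0, d;
  d = (warped[1] - warped[0]) / h - dref[0];
  ss += d * d;
  for (int i = 1; i < n - 1; ++i) {
    d = (warped[i + 1] - warped[i - 1]) / (2.0 * h) - dref[i];
    ss += d * d;
  }
  d = (warped[n - 1] - warped[n - 2]) / h - dref[n - 1];
  ss += d * d;
  return std::sqrt(ss);
}

// [[Rcpp::export]]
NumericVector cpp_apply_warp(NumericVector subject, double t1, double t2,
                             double t1ref, double t2ref) {
  int n = subject.size();
  NumericVector out(n);
  warp_values(subject.begin(), n, t1, t2, t1ref, t2ref, out.begin());
  return out;
}

// [[Rcpp::export]]
double cpp_sync_cost(NumericVector subject, NumericVector dref, double t1,
                     double t2, double t1ref, double t2ref) {
  int n = subject.size();
  std::vector<double> w(n);
  warp_values(subject.begin(), n, t1, t2, t1ref, t2ref, w.data());
  return deriv_cost(w.data(), dref.begin(), n);
}

// Exhaustive lattice search over bound-respecting (t1, t2, t1ref, t2ref).
// Iteration is in lexicographic order of the tuple and only strict
// improvements are kept, so ties resolve to the smallest tuple.
// [[Rcpp::export]]
List cpp_grid_search(NumericVector subject, NumericVector dref,
                     double lo1, double hi1, double lo2, double hi2,
                     double resolution) {
  int n = subject.size();
  int n1 = (int)std::floor((hi1 - lo1) / resolution + 1.5);
  int n2 = (int)std::floor((hi2 - lo2) / resolution + 1.5);
  std::vector<double> g1(n1), g2(n2), w(n);
  for (int i = 0; i < n1; ++i) g1[i] = lo1 + i * resolution;
  for (int i = 0; i < n2; ++i) g2[i] = lo2 + i * resolution;

  double best = R_PosInf;
  double b1 = g1[0], b2 = g2[0], b1r = g1[0], b2r = g2[0];
  long n_eval = 0;
  for (int i1 = 0; i1 < n1; ++i1)
    for (int i2 = 0; i2 < n2; ++i2)
      for (int j1 = 0; j1 < n1; ++j1)
        for (int j2 = 0; j2 < n2; ++j2) {
          warp_values(subject.begin(), n, g1[i1], g2[i2], g1[j1], g2[j2],
                      w.data());
          double cost = deriv_cost(w.data(), dref.begin(), n);
          ++n_eval;
          if (cost < best) {
            best = cost;
            b1 = g1[i1]; b2 = g2[i2]; b1r = g1[j1]; b2r = g2[j2];
          }
        }
  return List::create(_["t1"] = b1, _["t2"] = b2, _["t1ref"] = b1r,
                      _["t2ref"] = b2r, _["cost"] = best,
                      _["n_eval"] = (double)n_eval);
}
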
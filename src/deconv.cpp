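#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sparse non-negative deconvolution of a single fluorescence trace under
// AR(2) dynamics: minimize over c
//     0.5 * sum_t w_t (y_t - c_t)^2 + lambda * sum_t (G c)_t
//     subject to (G c)_t >= 0,
// where (G c)_t = c_t - g1 c_{t-1} - g2 c_{t-2} is the spike signal.
// Solved by ADMM with the splitting s = G c.  The c-update solves the
// pentadiagonal SPD system (W + rho G'G) c = W y + rho G'(s - u) via a
// banded LDL' factorization, O(T) per iteration.

static void apply_G(const std::vector<double>& c, std::vector<double>& out,
                    double g1, double g2) {
  int T = c.size();
  for (int t = 0; t < T; ++t) {
    double v = c[t];
    if (t >= 1) v -= g1 * c[t - 1];
    if (t >= 2) v -= g2 * c[t - 2];
    out[t] = v;
  }
}

static void apply_Gt(const std::vector<double>& v, std::vector<double>& out,
                     double g1, double g2) {
  int T = v.size();
  for (int t = 0; t < T; ++t) {
    double x = v[t];
    if (t + 1 < T) x -= g1 * v[t + 1];
    if (t + 2 < T) x -= g2 * v[t + 2];
    out[t] = x;
  }
}

// banded LDL' of the pentadiagonal matrix M = W + rho * G'G
// (d0 = main diagonal, d1 = first sub, d2 = second sub)
struct PentaChol {
  std::vector<double> l1, l2, d;
  void factor(const std::vector<double>& w, double rho,
              double g1, double g2) {
    int T = w.size();
    l1.assign(T, 0.0); l2.assign(T, 0.0); d.assign(T, 0.0);
    std::vector<double> d0(T), s1(T, 0.0), s2(T, 0.0);
    // G'G entries: row t diagonal = 1 + g1^2 [t+1<T] + g2^2 [t+2<T]
    for (int t = 0; t < T; ++t) {
      double v = 1.0;
      if (t + 1 < T) v += g1 * g1;
      if (t + 2 < T) v += g2 * g2;
      d0[t] = w[t] + rho * v;
    }
    for (int t = 0; t < T - 1; ++t) {
      double v = -g1;                 // G[t+1,t] contribution with diag 1
      if (t + 2 < T) v += g1 * g2;    // (-g1)(-g2) overlap
      s1[t] = rho * v;                // M[t+1, t]
    }
    for (int t = 0; t < T - 2; ++t) s2[t] = rho * (-g2);
    for (int t = 0; t < T; ++t) {
      double dt = d0[t];
      if (t >= 1) dt -= l1[t - 1] * l1[t - 1] * d[t - 1];
      if (t >= 2) dt -= l2[t - 2] * l2[t - 2] * d[t - 2];
      d[t] = dt;
      if (t + 1 < T) {
        double v = s1[t];
        if (t >= 1) v -= l1[t - 1] * d[t - 1] * l2[t - 1];
        l1[t] = v / d[t];
      }
      if (t + 2 < T) l2[t] = s2[t] / d[t];
    }
  }
  void solve(const std::vector<double>& b, std::vector<double>& x) const {
    int T = b.size();
    // forward: L z = b
    for (int t = 0; t < T; ++t) {
      double v = b[t];
      if (t >= 1) v -= l1[t - 1] * x[t - 1];
      if (t >= 2) v -= l2[t - 2] * x[t - 2];
      x[t] = v;
    }
    // diagonal and backward: L' x = D^{-1} z
    for (int t = T - 1; t >= 0; --t) {
      double v = x[t] / d[t];
      if (t + 1 < T) v -= l1[t] * x[t + 1];
      if (t + 2 < T) v -= l2[t] * x[t + 2];
      x[t] = v;
    }
  }
};

// [[Rcpp::export]]
List deconv_admm(NumericVector y, double g1, double g2, NumericVector w,
                 double lambda, int maxit = 5000, double tol = 1e-11,
                 Nullable<NumericVector> c_warm = R_NilValue,
                 Nullable<NumericVector> u_warm = R_NilValue,
                 double rho_init = 1.0, double relax = 1.8) {
  int T = y.size();
  std::vector<double> yv(y.begin(), y.end());
  std::vector<double> wv(w.begin(), w.end());
  double rho = rho_init;
  std::vector<double> c(T, 0.0), s(T, 0.0), u(T, 0.0);
  if (c_warm.isNotNull()) {
    NumericVector cw(c_warm);
    std::copy(cw.begin(), cw.end(), c.begin());
    apply_G(c, s, g1, g2);
    for (int t = 0; t < T; ++t) if (s[t] < 0) s[t] = 0;
  }
  if (u_warm.isNotNull()) {
    NumericVector uw(u_warm);
    std::copy(uw.begin(), uw.end(), u.begin());
  }
  double yscale = 0.0;
  for (int t = 0; t < T; ++t) yscale = std::max(yscale, std::fabs(yv[t]));
  double atol = tol * std::max(1.0, yscale);

  PentaChol chol;
  chol.factor(wv, rho, g1, g2);
  std::vector<double> rhs(T), gc(T), gts(T), s_old(T), diff(T);
  bool converged = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    // c-update
    for (int t = 0; t < T; ++t) diff[t] = s[t] - u[t];
    apply_Gt(diff, gts, g1, g2);
    for (int t = 0; t < T; ++t) rhs[t] = wv[t] * yv[t] + rho * gts[t];
    chol.solve(rhs, c);
    apply_G(c, gc, g1, g2);
    // s-update with over-relaxation (prox of lambda*1's + indicator(s>=0))
    std::copy(s.begin(), s.end(), s_old.begin());
    for (int t = 0; t < T; ++t) {
      double gch = relax * gc[t] + (1.0 - relax) * s_old[t];
      double v = gch + u[t] - lambda / rho;
      s[t] = v > 0 ? v : 0;
      u[t] += gch - s[t];
    }
    double rprim = 0.0, rdual = 0.0;
    for (int t = 0; t < T; ++t) {
      rprim = std::max(rprim, std::fabs(gc[t] - s[t]));
      diff[t] = s[t] - s_old[t];
    }
    apply_Gt(diff, gts, g1, g2);
    for (int t = 0; t < T; ++t)
      rdual = std::max(rdual, rho * std::fabs(gts[t]));
    if (rprim < atol && rdual < atol) { converged = true; ++it; break; }
    // residual balancing every 20 iterations
    if ((it + 1) % 20 == 0) {
      if (rprim > 10.0 * rdual) {
        rho *= 2.0;
        for (int t = 0; t < T; ++t) u[t] *= 0.5;
        chol.factor(wv, rho, g1, g2);
      } else if (rdual > 10.0 * rprim) {
        rho *= 0.5;
        for (int t = 0; t < T; ++t) u[t] *= 2.0;
        chol.factor(wv, rho, g1, g2);
      }
    }
  }
  // final spike signal from the converged c (project tiny negatives)
  apply_G(c, gc, g1, g2);
  for (int t = 0; t < T; ++t) if (gc[t] < 0 && gc[t] > -atol) gc[t] = 0;
  double wrss = 0.0;
  for (int t = 0; t < T; ++t) {
    double r = yv[t] - c[t];
    wrss += wv[t] * r * r;
  }
  return List::create(_["c"] = NumericVector(c.begin(), c.end()),
                      _["s"] = NumericVector(gc.begin(), gc.end()),
                      _["u"] = NumericVector(u.begin(), u.end()),
                      _["wrss"] = wrss,
                      _["iters"] = it,
                      _["converged"] = converged,
                      _["rho"] = rho);
}
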
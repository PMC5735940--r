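// Exhaustive reference minimizer for the smallest network configuration
// (two genes feeding one regulator, sigmoid output): enumerates the
// non-convex coordinates (w11, w12, b1) on a regular grid and solves the
// remaining (w2, b2) subproblem -- one-feature logistic regression with an
// l1 penalty on w2, jointly convex -- exactly at every grid point via
// safeguarded Newton steps. Used by the test suite as an independent check
// that proximal-gradient training reaches the global optimum; never part of
// the fitting path.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double softplus(double u) {
  return u > 0 ? u + std::log1p(std::exp(-u)) : std::log1p(std::exp(u));
}

// mean cross-entropy of u = w2*h + b2 against y
static double ce(const std::vector<double>& h, const std::vector<double>& y,
                 double w2, double b2) {
  double s = 0.0;
  const int n = h.size();
  for (int i = 0; i < n; ++i) {
    double u = w2 * h[i] + b2;
    s += softplus(u) - y[i] * u;
  }
  return s / n;
}

// 1-D safeguarded Newton for b2 at fixed w2 (convex, both classes present).
static double solve_b2(const std::vector<double>& h,
                       const std::vector<double>& y, double w2, double b2) {
  const int n = h.size();
  for (int it = 0; it < 100; ++it) {
    double g = 0.0, hess = 0.0;
    for (int i = 0; i < n; ++i) {
      double p = 1.0 / (1.0 + std::exp(-(w2 * h[i] + b2)));
      g += p - y[i];
      hess += p * (1.0 - p);
    }
    g /= n; hess = hess / n + 1e-12;
    double step = g / hess;
    if (step > 10.0) step = 10.0;
    if (step < -10.0) step = -10.0;
    b2 -= step;
    if (std::fabs(g) < 1e-12) break;
  }
  return b2;
}

// Damped 2-D Newton on f(w2,b2) = CE + c2*s*w2 for a fixed sign branch s.
// Returns the objective value; w2/b2 updated in place. If the branch
// minimizer crosses to the wrong sign the caller's w2 = 0 case covers it.
static double solve_branch(const std::vector<double>& h,
                           const std::vector<double>& y, double c2, int s,
                           double& w2, double& b2) {
  const int n = h.size();
  double f = ce(h, y, w2, b2) + c2 * s * w2;
  for (int it = 0; it < 200; ++it) {
    double gw = c2 * s, gb = 0.0, Hww = 0.0, Hwb = 0.0, Hbb = 0.0;
    for (int i = 0; i < n; ++i) {
      double u = w2 * h[i] + b2;
      double p = 1.0 / (1.0 + std::exp(-u));
      double d = (p - y[i]) / n, wgt = p * (1.0 - p) / n;
      gw += d * h[i];
      gb += d;
      Hww += wgt * h[i] * h[i];
      Hwb += wgt * h[i];
      Hbb += wgt;
    }
    if (std::fabs(gw) < 1e-11 && std::fabs(gb) < 1e-11) break;
    double det = Hww * Hbb - Hwb * Hwb;
    double dw, db;
    if (det > 1e-14) {
      dw = -(Hbb * gw - Hwb * gb) / det;
      db = -(Hww * gb - Hwb * gw) / det;
    } else {               // near-singular curvature: gradient step
      dw = -gw; db = -gb;
    }
    double t = 1.0, decr = gw * dw + gb * db;  // negative by construction
    double fnew;
    for (int ls = 0; ls < 60; ++ls) {
      fnew = ce(h, y, w2 + t * dw, b2 + t * db) + c2 * s * (w2 + t * dw);
      if (fnew <= f + 1e-4 * t * decr) break;
      t *= 0.5;
    }
    if (fnew >= f - 1e-15) break;
    w2 += t * dw; b2 += t * db; f = fnew;
  }
  return f;
}

// [[Rcpp::export]]
List toy_grid_minimum(NumericMatrix X, NumericVector y, double lambda,
                      double alpha, double rho = 2.0, double lo = -3.0,
                      double hi = 3.0, double step = 0.05) {
  if (X.ncol() != 2) stop("toy oracle expects exactly 2 gene columns");
  const int n = X.nrow();
  std::vector<double> yy(y.begin(), y.end());
  const double c1 = alpha * lambda;                    // ridge on W1
  const double c2 = (1.0 - alpha) * lambda * std::sqrt(rho); // group l1
  const int m = (int) std::lround((hi - lo) / step) + 1;

  double best = R_PosInf, bw11 = 0, bw12 = 0, bb1 = 0, bw2 = 0, bb2 = 0;
  std::vector<double> z0(n), h(n);

  for (int i1 = 0; i1 < m; ++i1) {
    double w11 = lo + i1 * step;
    for (int i2 = 0; i2 < m; ++i2) {
      double w12 = lo + i2 * step;
      for (int i = 0; i < n; ++i) z0[i] = w11 * X(i, 0) + w12 * X(i, 1);
      double ridge = c1 * (w11 * w11 + w12 * w12);
      double w2p = 0.5, b2p = 0.0, w2m = -0.5, b2m = 0.0, b20 = 0.0;
      for (int i3 = 0; i3 < m; ++i3) {
        double b1 = lo + i3 * step;
        for (int i = 0; i < n; ++i) {
          double z = z0[i] + b1;
          h[i] = z > 0 ? z : 0.0;
        }
        // w2 = 0 case (exact boundary of both sign branches)
        b20 = solve_b2(h, yy, 0.0, b20);
        double f0 = ce(h, yy, 0.0, b20);
        // Subgradient dispatch: with g0 = dCE/dw2 at (0, b2*), the inner
        // convex objective has its minimum at w2 = 0 unless |g0| > c2, and
        // then only on the branch opposite in sign to g0.
        double g0 = 0.0;
        const double p0 = 1.0 / (1.0 + std::exp(-b20));
        for (int i = 0; i < n; ++i) g0 += (p0 - yy[i]) * h[i];
        g0 /= n;
        double f = f0, w2s = 0.0, b2s = b20;
        if (g0 + c2 < 0) {            // minimum on the positive branch
          if (w2p <= 0) { w2p = 0.5; b2p = b20; }
          double fp = solve_branch(h, yy, c2, +1, w2p, b2p);
          if (w2p > 0 && fp < f) { f = fp; w2s = w2p; b2s = b2p; }
        } else if (g0 - c2 > 0) {     // minimum on the negative branch
          if (w2m >= 0) { w2m = -0.5; b2m = b20; }
          double fm = solve_branch(h, yy, c2, -1, w2m, b2m);
          if (w2m < 0 && fm < f) { f = fm; w2s = w2m; b2s = b2m; }
        }
        f += ridge;
        if (f < best) {
          best = f; bw11 = w11; bw12 = w12; bb1 = b1; bw2 = w2s; bb2 = b2s;
        }
      }
    }
  }
  return List::create(_["objective"] = best, _["W1"] =
                        NumericVector::create(bw11, bw12),
                      _["b1"] = bb1, _["W2"] = bw2, _["b2"] = bb2);
}
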
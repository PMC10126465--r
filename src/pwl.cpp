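// Constrained four-phase piecewise-linear fit of a normalized germination
// trace.  Model (time tau measured from the first frame):
//   tau in [0,  T1): f = 1 + s1*tau                 (lag phase, slow leak)
//   tau in [T1, T2): f = i_lag   -> i_release       (rapid release, linear)
//   tau in [T2, T3): f = i_release -> 0             (cortex lysis, linear)
//   tau >= T3      : f = 0
// For fixed breakpoints the model is linear in (i_lag, i_release), so the
// profiled SSE is a 2-parameter convex QP with three linear constraints:
//   i_lag <= 1            (lag slope non-positive)
//   i_release >= 0        (lysis segment decreasing to zero)
//   s2 <= rho * s1        (release at least rho times steeper than leak)
// All segment sums are evaluated from prefix sums, giving O(1) SSE per
// breakpoint triple so that exhaustive enumeration stays cheap.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

namespace {

struct Prefix {
  std::vector<double> s1, st, stt, sy, syt, syy;
  explicit Prefix(const NumericVector& y, const std::vector<double>& tau) {
    const int n = y.size();
    s1.assign(n + 1, 0.0); st = s1; stt = s1; sy = s1; syt = s1; syy = s1;
    for (int k = 0; k < n; ++k) {
      s1[k + 1]  = s1[k] + 1.0;
      st[k + 1]  = st[k] + tau[k];
      stt[k + 1] = stt[k] + tau[k] * tau[k];
      sy[k + 1]  = sy[k] + y[k];
      syt[k + 1] = syt[k] + y[k] * tau[k];
      syy[k + 1] = syy[k] + y[k] * y[k];
    }
  }
  // inclusive index range [lo, hi]; empty when lo > hi
  inline double S1(int lo, int hi)  const { return s1[hi + 1]  - s1[lo]; }
  inline double St(int lo, int hi)  const { return st[hi + 1]  - st[lo]; }
  inline double Stt(int lo, int hi) const { return stt[hi + 1] - stt[lo]; }
  inline double Sy(int lo, int hi)  const { return sy[hi + 1]  - sy[lo]; }
  inline double Syt(int lo, int hi) const { return syt[hi + 1] - syt[lo]; }
  inline double Syy(int lo, int hi) const { return syy[hi + 1] - syy[lo]; }
};

struct QP {
  // Q(x, y) = Syy - 2*Say*x - 2*Sby*y + Saa*x^2 + 2*Sab*x*y + Sbb*y^2
  double Saa, Sbb, Sab, Say, Sby, Syy;
};

// accumulate the quadratic form for breakpoints (b1, b2, b3), 0-based frames
QP build_qp(const Prefix& P, const std::vector<double>& tau, int n,
            int b1, int b2, int b3) {
  QP q{0, 0, 0, 0, 0, 0};
  const double T1 = tau[b1], T2 = tau[b2];
  const double d2 = T2 - T1;

  // segment A: frames 0..b1, basis a = tau/T1, offset c0 = 1 - tau/T1
  {
    const int lo = 0, hi = b1;
    const double St = P.St(lo, hi), Stt = P.Stt(lo, hi);
    const double Sy = P.Sy(lo, hi), Syt = P.Syt(lo, hi);
    const double S1 = P.S1(lo, hi), Syy = P.Syy(lo, hi);
    q.Saa += Stt / (T1 * T1);
    q.Say += (Syt - St + Stt / T1) / T1;
    q.Syy += (Syy - 2.0 * Sy + S1) + 2.0 * (Syt - St) / T1 + Stt / (T1 * T1);
  }
  // segment B: frames b1+1..b2, u = (tau - T1)/d2, f = (1-u)*ilag + u*irel
  {
    const int lo = b1 + 1, hi = b2;
    const double S1 = P.S1(lo, hi);
    const double Su  = (P.St(lo, hi) - T1 * S1) / d2;
    const double Suu = (P.Stt(lo, hi) - 2.0 * T1 * P.St(lo, hi) +
                        T1 * T1 * S1) / (d2 * d2);
    const double Sy  = P.Sy(lo, hi);
    const double Suy = (P.Syt(lo, hi) - T1 * Sy) / d2;
    q.Saa += S1 - 2.0 * Su + Suu;
    q.Sbb += Suu;
    q.Sab += Su - Suu;
    q.Say += Sy - Suy;
    q.Sby += Suy;
    q.Syy += P.Syy(lo, hi);
  }
  // segment C: frames b2+1..b3, v = (tau - T2)/d3, f = (1-v)*irel
  {
    const int lo = b2 + 1, hi = b3;
    const double T3 = tau[b3], d3 = T3 - T2;
    const double S1 = P.S1(lo, hi);
    const double Sv  = (P.St(lo, hi) - T2 * S1) / d3;
    const double Svv = (P.Stt(lo, hi) - 2.0 * T2 * P.St(lo, hi) +
                        T2 * T2 * S1) / (d3 * d3);
    const double Sy  = P.Sy(lo, hi);
    const double Svy = (P.Syt(lo, hi) - T2 * Sy) / d3;
    q.Sbb += S1 - 2.0 * Sv + Svv;
    q.Sby += Sy - Svy;
    q.Syy += P.Syy(lo, hi);
  }
  // segment D: frames b3+1..n-1, f = 0
  if (b3 + 1 <= n - 1) q.Syy += P.Syy(b3 + 1, n - 1);
  return q;
}

inline double qval(const QP& q, double x, double y) {
  return q.Syy - 2.0 * q.Say * x - 2.0 * q.Sby * y +
         q.Saa * x * x + 2.0 * q.Sab * x * y + q.Sbb * y * y;
}

// minimize the QP subject to x <= 1, y >= 0, T1*y - (T1+rho*d2)*x + rho*d2 <= 0
// by enumerating the unconstrained optimum, single-active-constraint optima
// and constraint vertices (convex 2-D QP).
void solve_qp(const QP& q, double T1, double d2, double rho,
              double& best_sse, double& best_x, double& best_y) {
  const double A = T1 + rho * d2;           // g3: T1*y - A*x + rho*d2 <= 0
  const double tol = 1e-9;
  double cx[8], cy[8];
  int nc = 0;

  const double det = q.Saa * q.Sbb - q.Sab * q.Sab;
  const double scale = std::max(q.Saa * q.Sbb, q.Sab * q.Sab) + 1e-300;
  if (det > 1e-12 * scale) {                 // unconstrained optimum
    cx[nc] = (q.Say * q.Sbb - q.Sab * q.Sby) / det;
    cy[nc] = (q.Saa * q.Sby - q.Sab * q.Say) / det;
    ++nc;
  }
  if (q.Sbb > 1e-300) {                      // x = 1 active
    cx[nc] = 1.0; cy[nc] = (q.Sby - q.Sab) / q.Sbb; ++nc;
  }
  if (q.Saa > 1e-300) {                      // y = 0 active
    cx[nc] = q.Say / q.Saa; cy[nc] = 0.0; ++nc;
  }
  {                                          // g3 active: y = alpha*x + beta
    const double alpha = A / T1, beta = -rho * d2 / T1;
    const double a2 = q.Saa + 2.0 * q.Sab * alpha + q.Sbb * alpha * alpha;
    if (a2 > 1e-300) {
      const double a1 = 2.0 * (q.Sab * beta + q.Sbb * alpha * beta -
                               q.Say - q.Sby * alpha);
      const double x = -a1 / (2.0 * a2);
      cx[nc] = x; cy[nc] = alpha * x + beta; ++nc;
    }
  }
  cx[nc] = 1.0; cy[nc] = 1.0; ++nc;          // vertex g1 & g3 (also feasible)
  cx[nc] = 1.0; cy[nc] = 0.0; ++nc;          // vertex g1 & g2
  cx[nc] = rho * d2 / A; cy[nc] = 0.0; ++nc; // vertex g2 & g3

  best_sse = std::numeric_limits<double>::infinity();
  best_x = 1.0; best_y = 1.0;
  for (int i = 0; i < nc; ++i) {
    const double x = cx[i], y = cy[i];
    if (x > 1.0 + tol) continue;
    if (y < -tol) continue;
    if (T1 * y - A * x + rho * d2 > tol * (1.0 + A)) continue;
    const double v = qval(q, x, y);
    if (v < best_sse) { best_sse = v; best_x = x; best_y = y; }
  }
  if (best_sse < 0.0) best_sse = 0.0;        // guard cancellation
}

} // namespace

// [[Rcpp::export(name = ".pwl_sse_triple")]]
List pwl_sse_triple(NumericVector y, NumericVector t,
                    int b1, int b2, int b3, double rho) {
  const int n = y.size();
  if (!(b1 >= 1 && b1 < b2 && b2 < b3 && b3 <= n - 1))
    stop("breakpoints must satisfy 1 <= b1 < b2 < b3 <= n-1 (0-based)");
  std::vector<double> tau(n);
  for (int k = 0; k < n; ++k) tau[k] = t[k] - t[0];
  Prefix P(y, tau);
  QP q = build_qp(P, tau, n, b1, b2, b3);
  double sse, x, yy;
  solve_qp(q, tau[b1], tau[b2] - tau[b1], rho, sse, x, yy);
  return List::create(_["sse"] = sse, _["i_lag"] = x, _["i_release"] = yy);
}

// Enumerate all ordered breakpoint triples drawn from the candidate index
// set `idx` (0-based frame indices, sorted, all in 1..n-1).  Ties in SSE are
// broken toward the lexicographically smallest (b1, b2, b3) by scanning in
// lexicographic order with strict improvement.
// [[Rcpp::export(name = ".pwl_search")]]
List pwl_search(NumericVector y, NumericVector t, IntegerVector idx,
                double rho) {
  const int n = y.size();
  if (n < 8) stop("trace shorter than 8 frames");
  const int m = idx.size();
  for (int i = 0; i < m; ++i) {
    if (idx[i] < 1 || idx[i] > n - 1) stop("candidate index out of range");
    if (i > 0 && idx[i] <= idx[i - 1]) stop("candidate indices must be sorted");
  }
  if (m < 3) stop("need at least 3 candidate breakpoints");

  std::vector<double> tau(n);
  for (int k = 0; k < n; ++k) tau[k] = t[k] - t[0];
  Prefix P(y, tau);

  double best = std::numeric_limits<double>::infinity();
  int B1 = -1, B2 = -1, B3 = -1;
  double bx = NA_REAL, by = NA_REAL;
  for (int i = 0; i < m - 2; ++i) {
    for (int j = i + 1; j < m - 1; ++j) {
      for (int k = j + 1; k < m; ++k) {
        const int b1 = idx[i], b2 = idx[j], b3 = idx[k];
        QP q = build_qp(P, tau, n, b1, b2, b3);
        double sse, x, yy;
        solve_qp(q, tau[b1], tau[b2] - tau[b1], rho, sse, x, yy);
        if (sse < best) { best = sse; B1 = b1; B2 = b2; B3 = b3;
                          bx = x; by = yy; }
      }
    }
  }
  return List::create(_["b1"] = B1, _["b2"] = B2, _["b3"] = B3,
                      _["sse"] = best, _["i_lag"] = bx, _["i_release"] = by);
}
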
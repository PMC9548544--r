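#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// One-compartment zero-order-infusion superposition at time t for one subject.
// rate[d] = amount/duration (mg/h). During an infusion the contribution is
// (R0/CL)(1 - exp(-k te)); after the end it decays exponentially.
static inline double conc_at(const double *d_time, const double *d_dur,
                             const double *d_rate, int nd,
                             double t, double k, double cl) {
  double c = 0.0;
  for (int d = 0; d < nd; ++d) {
    double rel = t - d_time[d];
    if (rel <= 0.0) continue;
    double te = rel < d_dur[d] ? rel : d_dur[d];
    c += d_rate[d] / cl * (1.0 - std::exp(-k * te)) * std::exp(-k * (rel - te));
  }
  return c;
}

struct SubjCtx {
  const double *ot, *oy;
  int no;
  const double *dt, *dd, *dr;
  int nd;
  double tvcl, v, omega, s1, s2;
};

// -2 log joint density of (y_i, eta), dropping all log(2*pi) terms.
static double h_eta(double eta, const SubjCtx &s, bool with_prior) {
  double cl = s.tvcl * std::exp(eta);
  double k = cl / s.v;
  double acc = 0.0;
  for (int j = 0; j < s.no; ++j) {
    double f = conc_at(s.dt, s.dd, s.dr, s.nd, s.ot[j], k, cl);
    double var = s.s2 * s.s2 + s.s1 * s.s1 * f * f;
    if (var <= 0.0) return 1e300;
    double r = s.oy[j] - f;
    acc += std::log(var) + r * r / var;
  }
  if (with_prior)
    acc += 2.0 * std::log(s.omega) + eta * eta / (s.omega * s.omega);
  return acc;
}

// Brent's localmin on [a, b].
static double brent_min(const SubjCtx &s, double a, double b, double tol,
                        double *fmin) {
  const double gold = 0.3819660112501051;
  const double eps = std::sqrt(2.220446049250313e-16);
  double x = 0.0;  // initialize at eta = 0 (inside [a,b] by construction)
  if (x <= a || x >= b) x = a + gold * (b - a);
  double w = x, vv = x;
  double fx = h_eta(x, s, true), fw = fx, fv = fx;
  double d = 0.0, e = 0.0;
  for (int iter = 0; iter < 200; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = eps * std::fabs(x) + tol / 3.0;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - vv) * (fx - fw);
      double p = (x - vv) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = d;
      if (!(std::fabs(p) >= std::fabs(0.5 * q * etemp) || p <= q * (a - x) ||
            p >= q * (b - x))) {
        d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm - x >= 0 ? tol1 : -tol1);
        golden = false;
      }
    }
    if (golden) {
      e = (x >= xm) ? a - x : b - x;
      d = gold * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + (d >= 0 ? tol1 : -tol1);
    double fu = h_eta(u, s, true);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      vv = w; fv = fw; w = x; fw = fx; x = u; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) {
        vv = w; fv = fw; w = u; fw = fu;
      } else if (fu <= fv || vv == x || vv == w) {
        vv = u; fv = fu;
      }
    }
  }
  *fmin = fx;
  return x;
}

// FOCE/Laplace objective function value. Constant-free convention: every
// log(2*pi) is dropped, so OFV = sum_i [-2 log integral p(y_i|eta) p(eta) deta]
// - n_obs_i * log(2*pi), approximated at the conditional mode.
// [[Rcpp::export]]
List foce_ofv_cpp(NumericVector tvcl, double v, double omega, double s1,
                  double s2, NumericVector obs_time, NumericVector obs_y,
                  IntegerVector obs_off, IntegerVector obs_len,
                  NumericVector dose_time, NumericVector dose_dur,
                  NumericVector dose_rate, IntegerVector dose_off,
                  IntegerVector dose_len, double eta_mult, double tol,
                  bool want_detail) {
  int ns = tvcl.size();
  double ofv = 0.0;
  NumericVector eta(ns), hess(ns);
  bool bad = false;
  for (int i = 0; i < ns; ++i) {
    SubjCtx s;
    s.ot = &obs_time[0] + obs_off[i];
    s.oy = &obs_y[0] + obs_off[i];
    s.no = obs_len[i];
    s.dt = &dose_time[0] + dose_off[i];
    s.dd = &dose_dur[0] + dose_off[i];
    s.dr = &dose_rate[0] + dose_off[i];
    s.nd = dose_len[i];
    s.tvcl = tvcl[i];
    s.v = v;
    s.omega = omega;
    s.s1 = s1;
    s.s2 = s2;
    if (omega <= 1e-10) {
      // degenerate random effect: fixed-effects -2LL (constant-free)
      double f0 = h_eta(0.0, s, false);
      ofv += f0;
      eta[i] = 0.0;
      hess[i] = NA_REAL;
      if (f0 >= 1e299) bad = true;
      continue;
    }
    double bound = eta_mult * omega;
    double fmin;
    double ehat = brent_min(s, -bound, bound, tol, &fmin);
    double d = std::max(1e-5, 1e-4 * std::fabs(ehat));
    double fp = h_eta(ehat + d, s, true);
    double fm = h_eta(ehat - d, s, true);
    double h2 = (fp - 2.0 * fmin + fm) / (d * d);
    if (!(h2 > 0.0) || !std::isfinite(h2)) h2 = 2.0 / (omega * omega);
    ofv += fmin + std::log(h2 / 2.0);
    eta[i] = ehat;
    hess[i] = h2;
    if (fmin >= 1e299) bad = true;
  }
  if (bad || !std::isfinite(ofv)) ofv = 1e300;
  if (want_detail)
    return List::create(_["ofv"] = ofv, _["eta"] = eta, _["hess"] = hess);
  return List::create(_["ofv"] = ofv);
}

// Evaluate the orthonormal Hermite polynomial p_n and its derivative at z
// with periodic rescaling (values grow like exp(z^2/2)); returns the
// Newton ratio p_n/p_n' and log|p_n'| for the weight.
static void hermite_eval(int n, double z, double *ratio, double *log_pp) {
  const double PIM4 = 0.7511255444649425;  // pi^(-1/4)
  double p1 = PIM4, p2 = 0.0, log_scale = 0.0;
  for (int j = 0; j < n; ++j) {
    double p3 = p2;
    p2 = p1;
    p1 = z * std::sqrt(2.0 / (j + 1)) * p2 -
         std::sqrt((double)j / (j + 1)) * p3;
    double a = std::fabs(p1) > std::fabs(p2) ? std::fabs(p1) : std::fabs(p2);
    if (a > 1e100) {
      p1 /= a;
      p2 /= a;
      log_scale += std::log(a);
    }
  }
  double pp = std::sqrt(2.0 * (double)n) * p2;
  *ratio = p1 / pp;
  *log_pp = std::log(std::fabs(pp)) + log_scale;
}

// number of eigenvalues of the Hermite Jacobi matrix below lambda
// (Sturm / LDL^T sign count; off-diagonals b_j^2 = j/2)
static int sturm_count(int n, double lambda) {
  int cnt = 0;
  double d = -lambda;
  if (d < 0) ++cnt;
  for (int j = 1; j < n; ++j) {
    double b2 = 0.5 * j;
    if (d == 0.0) d = 1e-300;
    d = -lambda - b2 / d;
    if (d < 0) ++cnt;
  }
  return cnt;
}

// Gauss-Hermite nodes and weights (physicists' convention: integral of
// exp(-x^2) f(x) dx = sum w_i f(x_i)). Nodes are the eigenvalues of the
// Jacobi matrix, located one by one with Sturm-sequence bisection (robust
// for arbitrarily large rules) and polished by Newton on the scaled
// orthonormal recurrence; weights come from the derivative value.
// [[Rcpp::export]]
List gauss_hermite_cpp(int n) {
  if (n < 1) stop("n must be >= 1");
  NumericVector x(n), w(n);
  double hi0 = std::sqrt(2.0 * n + 2.0);
  int m = (n + 1) / 2;
  for (int k = 0; k < m; ++k) {
    // k-th largest eigenvalue = eigenvalue with index n-1-k (ascending)
    int idx = n - 1 - k;
    double lo = 0.0, hi = hi0;
    if (2 * m != n && k == m - 1 && n % 2 == 1) {
      x[k] = 0.0;  // odd rules have a node exactly at the origin
    } else {
      for (int it = 0; it < 80; ++it) {
        double mid = 0.5 * (lo + hi);
        if (sturm_count(n, mid) <= idx) lo = mid; else hi = mid;
        if (hi - lo < 1e-12 * hi0) break;
      }
      x[k] = 0.5 * (lo + hi);
    }
    double ratio, log_pp;
    for (int it = 0; it < 10; ++it) {  // Newton polish
      hermite_eval(n, x[k], &ratio, &log_pp);
      x[k] -= ratio;
      if (std::fabs(ratio) < 1e-15 * (1.0 + std::fabs(x[k]))) break;
    }
    hermite_eval(n, x[k], &ratio, &log_pp);
    double log_w = std::log(2.0) - 2.0 * log_pp;
    w[k] = std::exp(log_w);
    x[n - 1 - k] = -x[k];
    w[n - 1 - k] = w[k];
  }
  return List::create(_["nodes"] = x, _["weights"] = w);
}
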
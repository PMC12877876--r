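// Dynamic-programming likelihood kernels for mutation-annotated trees.
//
// Messages P(nu | tau_s) are tabulated on a shared uniform time grid
// (backwards time, observation at node 0). Integrals over branch end times
// use the trapezoidal rule restricted to grid nodes <= tau_s. All messages
// are stored as logs; linear-space accumulation is max-shifted per message.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// phi(t) = 2 q t - 2 log((1-rho-q) e^{-(1-q)t} + rho);
// Lambda(tau_s, tau_e) = phi(tau_s) - phi(tau_e).
static inline double phi_fun(double t, double q, double rho) {
  return 2.0 * q * t -
         2.0 * std::log((1.0 - rho - q) * std::exp(-(1.0 - q) * t) + rho);
}

// psi(t) = -(1-q) t - 2 log((1-rho-q) e^{-(1-q)t} + rho);
// exp(psi(tau_s) - psi(tau_e)) = e^{-(1+q)(tau_s-tau_e)} e^{Lambda}.
static inline double psi_fun(double t, double q, double rho) {
  return -(1.0 - q) * t -
         2.0 * std::log((1.0 - rho - q) * std::exp(-(1.0 - q) * t) + rho);
}

// Coefficients of the generation sum: u_i = P(m|i)/i!, so that
// sum_i P(m|i) p1(i|.) = e^{-(1+q)(ts-te)} * sum_i u_i Lambda^i.
// Stored max-shifted: u[i] = exp(logu[i] - shift).
struct GenCoef {
  std::vector<double> u;     // shifted linear coefficients
  std::vector<double> logu;  // absolute log coefficients
  double shift;              // max log coefficient (NEG_INF if all zero)
};

static GenCoef gen_coef(int m, double mu, int imax) {
  GenCoef C;
  C.u.resize(imax + 1);
  C.logu.resize(imax + 1);
  double mx = NEG_INF;
  for (int i = 0; i <= imax; ++i) {
    double lu;
    if (mu == 0.0) {
      lu = (m == 0) ? -R::lgammafn(i + 1.0) : NEG_INF;
    } else {
      lu = -(i + 1.0) * mu + m * std::log((i + 1.0) * mu) -
           R::lgammafn(m + 1.0) - R::lgammafn(i + 1.0);
    }
    C.logu[i] = lu;
    if (lu > mx) mx = lu;
  }
  C.shift = mx;
  for (int i = 0; i <= imax; ++i) {
    C.u[i] = (mx == NEG_INF) ? 0.0 : std::exp(C.logu[i] - mx);
  }
  return C;
}

// log sum_i exp(logu[i]) * lam^i, numerically safe for any lam >= 0.
static double logS_safe(const std::vector<double>& logu, double lam) {
  int n = (int)logu.size();
  if (lam <= 0.0) return logu[0];
  double llam = std::log(lam);
  double mx = NEG_INF;
  for (int i = 0; i < n; ++i) {
    double v = logu[i] + i * llam;
    if (v > mx) mx = v;
  }
  if (mx == NEG_INF) return NEG_INF;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(logu[i] + i * llam - mx);
  return mx + std::log(s);
}

// Decide whether the fast (linear-space Horner) path is safe from overflow:
// the largest intermediate is bounded by exp(maxterm + (1+q) T) with
// maxterm the largest shifted series term at the maximal Lambda.
static bool fast_path_ok(const GenCoef& C, double lam_max, double q, double T) {
  if (C.shift == NEG_INF) return true;  // degenerate, handled upstream
  double llam = (lam_max > 1.0) ? std::log(lam_max) : 0.0;
  double maxterm = 0.0;
  int n = (int)C.u.size();
  for (int i = 0; i < n; ++i) {
    double v = (C.logu[i] - C.shift) + i * llam;
    if (v > maxterm) maxterm = v;
  }
  return maxterm + (1.0 + q) * T < 680.0;
}

static void pendant_logmsg_impl(int m, const NumericVector& t, double q,
                                double mu, double rho, int imax,
                                std::vector<double>& out) {
  int G1 = t.size();
  out.assign(G1, NEG_INF);
  GenCoef C = gen_coef(m, mu, imax);
  if (C.shift == NEG_INF) return;  // mu = 0 with m > 0
  std::vector<double> phi(G1);
  for (int g = 0; g < G1; ++g) phi[g] = phi_fun(t[g], q, rho);
  double lam_max = 0.0;
  for (int g = 0; g < G1; ++g) {
    double l = phi[g] - phi[0];
    if (l > lam_max) lam_max = l;
  }
  double lrho = std::log(rho);
  bool fast = fast_path_ok(C, lam_max, q, t[G1 - 1]);
  for (int g = 0; g < G1; ++g) {
    double lam = phi[g] - phi[0];
    if (lam < 0.0) lam = 0.0;
    double logS;
    if (fast) {
      double S = C.u[imax];
      for (int i = imax - 1; i >= 0; --i) S = S * lam + C.u[i];
      logS = (S > 0.0) ? std::log(S) + C.shift : NEG_INF;
    } else {
      logS = logS_safe(C.logu, lam);
    }
    out[g] = lrho - (1.0 + q) * t[g] + logS;
  }
}

static void internal_logmsg_impl(int m, const std::vector<double>& logA,
                                 const std::vector<double>& logB,
                                 const NumericVector& t, double q, double mu,
                                 double rho, int imax,
                                 std::vector<double>& out) {
  int G1 = t.size();
  double dt = (G1 > 1) ? (t[1] - t[0]) : 0.0;
  out.assign(G1, NEG_INF);
  GenCoef C = gen_coef(m, mu, imax);
  if (C.shift == NEG_INF) return;
  std::vector<double> logK(G1);
  double Kmax = NEG_INF;
  for (int h = 0; h < G1; ++h) {
    logK[h] = M_LN2 + logA[h] + logB[h];
    if (logK[h] > Kmax) Kmax = logK[h];
  }
  if (Kmax == NEG_INF) return;
  std::vector<double> phi(G1);
  for (int g = 0; g < G1; ++g) phi[g] = phi_fun(t[g], q, rho);
  double lam_max = 0.0;
  for (int g = 0; g < G1; ++g) {
    double l = phi[g] - phi[0];
    if (l > lam_max) lam_max = l;
  }
  double T = t[G1 - 1];
  if (fast_path_ok(C, lam_max, q, T)) {
    std::vector<double> c(G1), E(G1), lam(G1), S(G1);
    for (int h = 0; h < G1; ++h) {
      E[h] = std::exp(-(1.0 + q) * t[h]);
      double k = std::isfinite(logK[h]) ? std::exp(logK[h] - Kmax) : 0.0;
      c[h] = k * std::exp((1.0 + q) * t[h]);
    }
    for (int g = 1; g < G1; ++g) {
      for (int h = 0; h <= g; ++h) {
        double l = phi[g] - phi[h];
        lam[h] = (l > 0.0) ? l : 0.0;
      }
      for (int h = 0; h <= g; ++h) S[h] = C.u[imax];
      for (int i = imax - 1; i >= 0; --i) {
        double ui = C.u[i];
        for (int h = 0; h <= g; ++h) S[h] = S[h] * lam[h] + ui;
      }
      double acc = 0.5 * (S[0] * c[0] + S[g] * c[g]);
      for (int h = 1; h < g; ++h) acc += S[h] * c[h];
      double val = acc * dt * E[g];
      out[g] = (val > 0.0) ? std::log(val) + Kmax + C.shift : NEG_INF;
    }
  } else {
    // Safe path: per-pair log-space evaluation with log-sum-exp over the
    // quadrature nodes. Slower; used when e^{(1+q)T} or the generation
    // series would overflow in linear space (very deep grids).
    double ldt = std::log(dt);
    std::vector<double> lt(G1);
    for (int g = 1; g < G1; ++g) {
      double mx = NEG_INF;
      for (int h = 0; h <= g; ++h) {
        double l = phi[g] - phi[h];
        if (l < 0.0) l = 0.0;
        double v = logS_safe(C.logu, l) - (1.0 + q) * (t[g] - t[h]) + logK[h] +
                   ldt + ((h == 0 || h == g) ? -M_LN2 : 0.0);
        lt[h] = v;
        if (v > mx) mx = v;
      }
      if (mx == NEG_INF) continue;
      double s = 0.0;
      for (int h = 0; h <= g; ++h) s += std::exp(lt[h] - mx);
      out[g] = mx + std::log(s);
    }
  }
}

static double root_loglik_impl(const std::vector<double>& logA,
                               const std::vector<double>& logB, double dt) {
  int G1 = (int)logA.size();
  double Kmax = NEG_INF;
  std::vector<double> logK(G1);
  for (int g = 0; g < G1; ++g) {
    logK[g] = M_LN2 + logA[g] + logB[g];
    if (logK[g] > Kmax) Kmax = logK[g];
  }
  if (Kmax == NEG_INF) return NEG_INF;
  double acc = 0.0;
  for (int g = 0; g < G1; ++g) {
    double w = (g == 0 || g == G1 - 1) ? 0.5 : 1.0;
    acc += w * (std::isfinite(logK[g]) ? std::exp(logK[g] - Kmax) : 0.0);
  }
  return std::log(acc * dt) + Kmax;
}

// [[Rcpp::export]]
NumericVector cpp_pendant_logmsg(int m, NumericVector t, double q, double mu,
                                 double rho, int imax) {
  std::vector<double> out;
  pendant_logmsg_impl(m, t, q, mu, rho, imax, out);
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
NumericVector cpp_internal_logmsg(int m, NumericVector logA, NumericVector logB,
                                  NumericVector t, double q, double mu,
                                  double rho, int imax) {
  std::vector<double> a(logA.begin(), logA.end());
  std::vector<double> b(logB.begin(), logB.end());
  std::vector<double> out;
  internal_logmsg_impl(m, a, b, t, q, mu, rho, imax, out);
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
double cpp_root_loglik(NumericVector logA, NumericVector logB, double dt) {
  std::vector<double> a(logA.begin(), logA.end());
  std::vector<double> b(logB.begin(), logB.end());
  return root_loglik_impl(a, b, dt);
}

// Full-tree likelihood. `porder` lists internal node ids children-first with
// the root last; `children` row (nd - ntip) holds the two child node ids of
// internal node nd; `edge_m` holds the mutation count of the branch above
// each node (unused entry for the root).
// [[Rcpp::export]]
double cpp_tree_loglik(IntegerVector porder, IntegerMatrix children,
                       NumericVector edge_m, int ntip, NumericVector t,
                       double q, double mu, double rho, int imax) {
  int G1 = t.size();
  double dt = (G1 > 1) ? (t[1] - t[0]) : 0.0;
  int nnode = porder.size();
  int nmax = ntip + nnode;
  int root = ntip + 1;
  std::vector<std::vector<double>> msg(nmax + 1);
  for (int nd = 1; nd <= ntip; ++nd) {
    pendant_logmsg_impl((int)edge_m[nd - 1], t, q, mu, rho, imax, msg[nd]);
  }
  for (int k = 0; k < nnode; ++k) {
    int nd = porder[k];
    int c1 = children(nd - ntip - 1, 0);
    int c2 = children(nd - ntip - 1, 1);
    if (nd == root) {
      return root_loglik_impl(msg[c1], msg[c2], dt);
    }
    internal_logmsg_impl((int)edge_m[nd - 1], msg[c1], msg[c2], t, q, mu, rho,
                         imax, msg[nd]);
    std::vector<double>().swap(msg[c1]);
    std::vector<double>().swap(msg[c2]);
  }
  return NA_REAL;  // unreachable for a valid layout
}

// ---------------------------------------------------------------------------
// Constant-rate molecular-clock comparison model: the per-branch factor is
// Pois(m; mu_t (tau_s - tau_e)) times the probability that the window is
// bridged by a lineage with no sampled side offspring,
// e^{-(1+q)(ts-te)} e^{Lambda} = exp(psi(ts) - psi(te)).
// ---------------------------------------------------------------------------

static void clock_pendant_impl(int m, const NumericVector& t, double q,
                               double mu_t, double rho,
                               std::vector<double>& out) {
  int G1 = t.size();
  out.assign(G1, NEG_INF);
  double lrho = std::log(rho);
  double psi0 = psi_fun(t[0], q, rho);
  for (int g = 0; g < G1; ++g) {
    double lp = R::dpois(m, mu_t * t[g], 1);
    out[g] = lrho + lp + psi_fun(t[g], q, rho) - psi0;
  }
}

static void clock_internal_impl(int m, const std::vector<double>& logA,
                                const std::vector<double>& logB,
                                const NumericVector& t, double q, double mu_t,
                                double rho, std::vector<double>& out) {
  int G1 = t.size();
  double dt = (G1 > 1) ? (t[1] - t[0]) : 0.0;
  out.assign(G1, NEG_INF);
  std::vector<double> logK(G1);
  double Kmax = NEG_INF;
  for (int h = 0; h < G1; ++h) {
    logK[h] = M_LN2 + logA[h] + logB[h];
    if (logK[h] > Kmax) Kmax = logK[h];
  }
  if (Kmax == NEG_INF) return;
  // Poisson factor depends on the window only through g - h.
  std::vector<double> logP(G1);
  double sP = NEG_INF;
  for (int d = 0; d < G1; ++d) {
    logP[d] = R::dpois(m, mu_t * dt * d, 1);
    if (logP[d] > sP) sP = logP[d];
  }
  if (sP == NEG_INF) return;
  std::vector<double> P(G1), c(G1), psi(G1);
  for (int d = 0; d < G1; ++d) {
    P[d] = std::isfinite(logP[d]) ? std::exp(logP[d] - sP) : 0.0;
  }
  for (int h = 0; h < G1; ++h) {
    psi[h] = psi_fun(t[h], q, rho);
    double k = std::isfinite(logK[h]) ? std::exp(logK[h] - Kmax) : 0.0;
    c[h] = k * std::exp(-psi[h]);
  }
  for (int g = 1; g < G1; ++g) {
    double acc = 0.5 * (P[g] * c[0] + P[0] * c[g]);
    for (int h = 1; h < g; ++h) acc += P[g - h] * c[h];
    double val = acc * dt * std::exp(psi[g]);
    out[g] = (val > 0.0) ? std::log(val) + Kmax + sP : NEG_INF;
  }
}

// [[Rcpp::export]]
NumericVector cpp_clock_pendant_logmsg(int m, NumericVector t, double q,
                                       double mu_t, double rho) {
  std::vector<double> out;
  clock_pendant_impl(m, t, q, mu_t, rho, out);
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
NumericVector cpp_clock_internal_logmsg(int m, NumericVector logA,
                                        NumericVector logB, NumericVector t,
                                        double q, double mu_t, double rho) {
  std::vector<double> a(logA.begin(), logA.end());
  std::vector<double> b(logB.begin(), logB.end());
  std::vector<double> out;
  clock_internal_impl(m, a, b, t, q, mu_t, rho, out);
  return NumericVector(out.begin(), out.end());
}

// [[Rcpp::export]]
double cpp_clock_tree_loglik(IntegerVector porder, IntegerMatrix children,
                             NumericVector edge_m, int ntip, NumericVector t,
                             double q, double mu_t, double rho) {
  int G1 = t.size();
  double dt = (G1 > 1) ? (t[1] - t[0]) : 0.0;
  int nnode = porder.size();
  int nmax = ntip + nnode;
  int root = ntip + 1;
  std::vector<std::vector<double>> msg(nmax + 1);
  for (int nd = 1; nd <= ntip; ++nd) {
    clock_pendant_impl((int)edge_m[nd - 1], t, q, mu_t, rho, msg[nd]);
  }
  for (int k = 0; k < nnode; ++k) {
    int nd = porder[k];
    int c1 = children(nd - ntip - 1, 0);
    int c2 = children(nd - ntip - 1, 1);
    if (nd == root) {
      return root_loglik_impl(msg[c1], msg[c2], dt);
    }
    clock_internal_impl((int)edge_m[nd - 1], msg[c1], msg[c2], t, q, mu_t, rho,
                        msg[nd]);
    std::vector<double>().swap(msg[c1]);
    std::vector<double>().swap(msg[c2]);
  }
  return NA_REAL;
}
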
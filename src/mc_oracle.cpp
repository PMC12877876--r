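// Forward Monte-Carlo oracle for the hidden-generation distribution.
//
// Estimates, by direct simulation of the birth-death process, the expected
// number of lineages that start at backward time tau_s, are alive at tau_e
// with exactly i divisions along their path, and whose side clades all lack
// sampled descendants at the observation time. This expectation equals
// p1^{(rho)}(i | tau_s, tau_e).
//
// Uses R's RNG (seed via set.seed() in R).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_mc_p1(double tau_s, double tau_e, double q, double rho,
                        int n_reps, int i_cap) {
  if (tau_e < 0 || tau_s < tau_e) stop("require 0 <= tau_e <= tau_s");
  const double s_obs = tau_s;          // forward time of observation
  const double s_e = tau_s - tau_e;    // forward time corresponding to tau_e
  const double total_rate = 1.0 + q;
  const double p_birth = 1.0 / total_rate;
  const size_t node_cap = 4000000;     // guards against runaway growth

  NumericMatrix res(2, i_cap + 1);     // row 0: sum counts, row 1: sum squares
  std::vector<double> tb, te;
  std::vector<int> parent, c1, c2;
  std::vector<char> extant, hs;
  std::vector<int> stack, cnt(i_cap + 1);
  RNGScope scope;

  for (int rep = 0; rep < n_reps; ++rep) {
    tb.clear(); te.clear(); parent.clear(); c1.clear(); c2.clear();
    extant.clear();
    tb.push_back(0.0); te.push_back(0.0); parent.push_back(-1);
    c1.push_back(-1); c2.push_back(-1); extant.push_back(0);
    stack.clear();
    stack.push_back(0);
    bool aborted = false;
    while (!stack.empty()) {
      int id = stack.back();
      stack.pop_back();
      double d = tb[id] + R::exp_rand() / total_rate;
      if (d >= s_obs) {
        te[id] = s_obs;
        extant[id] = 1;
        continue;
      }
      te[id] = d;
      if (unif_rand() < p_birth) {
        if (tb.size() + 2 > node_cap) { aborted = true; break; }
        for (int k = 0; k < 2; ++k) {
          int nid = (int)tb.size();
          tb.push_back(d); te.push_back(d); parent.push_back(id);
          c1.push_back(-1); c2.push_back(-1); extant.push_back(0);
          if (k == 0) c1[id] = nid; else c2[id] = nid;
          stack.push_back(nid);
        }
      }
    }
    if (aborted) stop("simulated clade exceeded the node cap; reduce tau_s");
    int n = (int)tb.size();
    hs.assign(n, 0);
    for (int id = n - 1; id >= 0; --id) {
      if (extant[id]) {
        hs[id] = (unif_rand() < rho) ? 1 : 0;
      } else if (c1[id] >= 0) {
        hs[id] = (hs[c1[id]] || hs[c2[id]]) ? 1 : 0;
      }
    }
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int id = 0; id < n; ++id) {
      // alive at forward time s_e: born no later, ended strictly later
      // (extant cells have te == s_obs >= s_e; for tau_e == 0 they count)
      bool alive = tb[id] <= s_e && (extant[id] ? true : te[id] > s_e);
      if (!alive) continue;
      int i = 0;
      bool ok = true;
      int cur = id;
      while (parent[cur] >= 0) {
        int p = parent[cur];
        int sib = (c1[p] == cur) ? c2[p] : c1[p];
        if (hs[sib]) { ok = false; break; }
        ++i;
        cur = p;
      }
      if (ok && i <= i_cap) cnt[i] += 1;
    }
    for (int i = 0; i <= i_cap; ++i) {
      res(0, i) += cnt[i];
      res(1, i) += (double)cnt[i] * cnt[i];
    }
  }
  return res;
}
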
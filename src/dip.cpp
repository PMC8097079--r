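// Exact dip-statistic feasibility kernel.
//
// The dip of a sample is the smallest eps (in ecdf units) such that some
// unimodal cdf U -- convex left of its mode, concave right of it, with an
// atom permitted at the mode -- satisfies sup |Fn - U| <= eps. Working in
// count units (tube half-width e = n * eps), the constraints at the sorted
// points t_1..t_n are
//   U(t_i)  >= A_i = i - e        (post-jump lower bound)
//   U(t_i-) <= B_i = i - 1 + e    (pre-jump upper bound)
// A convex function through these tubes admits a pointwise-minimal
// envelope V built left to right: each settled point j emits a ray with
// the smallest slope compatible with convexity (the steepest chord from
// any earlier upper bound up to (t_j, V_j)), and V_i is the larger of A_i
// and the highest ray. The side is feasible up to m iff V_i <= B_i for all
// i <= m. The concave side is the mirror image. A candidate mode at t_m
// (atom there) or in a gap (t_m, t_m+1) joins the two sides; the join
// needs the minimal convex end value not to exceed the maximal concave
// start value.

#include <Rcpp.h>
using namespace Rcpp;

// Left (convex) pass in count units.
// Outputs, 1-based in R indexing convention (vectors of length n + 1):
//   V[i]    envelope value with the full anchor A_i            (i = 1..n)
//   rel[i]  minimal end value at t_i when t_i is the convex side's open
//           end (anchor relaxed to the pre-jump bound i - 1 - e)
//   ok[i]   TRUE iff V_k <= B_k for all k <= i (ok[0] = TRUE)
static void convex_pass(const std::vector<double>& t, int n, double e,
                        std::vector<double>& V, std::vector<double>& rel,
                        std::vector<int>& ok) {
  std::vector<double> S(n + 1, 0.0); // outgoing minimal slope at j
  V.assign(n + 1, 0.0);
  rel.assign(n + 1, 0.0);
  ok.assign(n + 1, 1);
  const double inf = std::numeric_limits<double>::infinity();
  for (int i = 1; i <= n; ++i) {
    double env = 0.0; // rays start at the baseline U >= 0
    for (int j = 1; j < i; ++j) {
      double r = V[j] + S[j] * (t[i] - t[j]);
      if (r > env) env = r;
    }
    double Ai = i - e;
    rel[i] = std::max(env, (double)(i - 1) - e);
    V[i] = std::max(env, Ai);
    double Bi = i - 1 + e;
    ok[i] = ok[i - 1] && (V[i] <= Bi + 1e-9);
    // minimal outgoing slope: steepest chord from an earlier upper bound
    double s = 0.0;
    for (int a = 1; a < i; ++a) {
      double dv = V[i] - ((double)(a - 1) + e);
      if (dv > 0) {
        double dt = t[i] - t[a];
        double cand = (dt > 0) ? dv / dt : inf;
        if (cand > s) s = cand;
      }
    }
    S[i] = s;
  }
}

// [[Rcpp::export(name = ".dip_feasible_cpp")]]
bool dip_feasible_cpp(NumericVector x, double e) {
  int n = x.size();
  std::vector<double> t(n + 1);
  for (int i = 0; i < n; ++i) t[i + 1] = x[i];
  std::vector<double> tm(n + 1); // mirrored: t -> -rev(t)
  for (int i = 1; i <= n; ++i) tm[i] = -t[n + 1 - i];

  std::vector<double> V, rel, Wm, relm;
  std::vector<int> okL, okRm;
  convex_pass(t, n, e, V, rel, okL);
  convex_pass(tm, n, e, Wm, relm, okRm);
  // mirror back: counts c -> n - c, index i -> n + 1 - i
  // full-anchor maximal concave start at t_i:  Wfull_i = n - Wm[n + 1 - i]
  // relaxed (atom at t_i): urel_i = n - relm[n + 1 - i]
  // suffix validity from i on: okR_i = okRm[n + 1 - i]
  auto Wfull = [&](int i) { return n - Wm[n + 1 - i]; };
  auto urel = [&](int i) { return n - relm[n + 1 - i]; };
  auto okR = [&](int i) { return i > n ? 1 : okRm[n + 1 - i]; };
  auto okLft = [&](int i) { return i < 1 ? 1 : okL[i]; };

  const double tol = 1e-9;
  // mode (atom) at data point t_m: the convex side open-ends at t_m with
  // a pre-jump value in [rel_m, B_m], the concave side starts there with
  // a post-jump value in [A_m, urel_m], and the atom joins them. A mode
  // strictly inside a gap is dominated by the adjacent data-point modes
  // (shifting the atom onto the nearer data point only relaxes the
  // envelope constraints), so scanning data points is exhaustive.
  (void)Wfull;
  for (int m = 1; m <= n; ++m) {
    if (!okLft(m - 1) || !okR(m + 1)) continue;
    double Bm = (double)(m - 1) + e;
    double Am = (double)m - e;
    if (rel[m] > Bm + tol) continue;      // convex end range empty
    if (urel(m) < Am - tol) continue;     // concave start range empty
    if (rel[m] <= urel(m) + tol) return true;
  }
  return false;
}
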
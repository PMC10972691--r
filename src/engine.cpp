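#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Distribution propagation p' = p^T exp(Q tau) by uniformization.
// Edges are (from, to, rate) with 0-based full-space indices; outrate[i] is the
// total exit rate of state i.  lambda must satisfy lambda >= max(outrate).
static void expm_dist(std::vector<double> &v,
                      const int *from, const int *to, const double *rate,
                      R_xlen_t ne,
                      const std::vector<double> &outrate,
                      double lambda, double tau) {
  const int n = (int)v.size();
  const double lt = lambda * tau;
  const int K = (int)(lt + 8.0 * std::sqrt(lt + 1.0) + 25.0);
  std::vector<double> x(v), y(n), acc(n, 0.0);
  double w = std::exp(-lt);
  for (int i = 0; i < n; ++i) acc[i] = w * x[i];
  for (int k = 1; k <= K; ++k) {
    for (int i = 0; i < n; ++i) y[i] = x[i] * (1.0 - outrate[i] / lambda);
    for (R_xlen_t e = 0; e < ne; ++e)
      y[to[e]] += x[from[e]] * (rate[e] / lambda);
    x.swap(y);
    w *= lt / k;
    for (int i = 0; i < n; ++i) acc[i] += w * x[i];
    if (w < 1e-280 && k > lt) break; // tail negligible
  }
  v.swap(acc);
}

// Exact blockwise mutation-configuration probabilities for one heterospecific
// pair (two diploids, four lineages) under a two-phase structured coalescent:
// a migration phase of scaled duration T (two demes, unidirectional migration)
// followed by a single ancestral phase run to absorption.  Mutation counts per
// branch-type class are embedded in the state (Poissonization), truncated at
// kmax with a sticky residual level, so the returned vector over count
// configurations sums to one.
//
// Phase-1 edge types: 1 coalescence in A, 2 coalescence in B, 3 migration
// (backwards) B->A, 4 migration A->B, 5 mutation.  Phase-2 types: 1
// coalescence (ancestral), 2 mutation.  Rates are base[type] * mult.
// [[Rcpp::export]]
NumericVector bsfs_engine_cpp(int n1,
                              IntegerVector e1_from, IntegerVector e1_to,
                              IntegerVector e1_type, NumericVector e1_mult,
                              NumericVector base1, double T, int p0,
                              IntegerVector proj, int n2,
                              IntegerVector e2_from, IntegerVector e2_to,
                              IntegerVector e2_type, NumericVector e2_mult,
                              NumericVector base2, IntegerVector e2_ptr,
                              IntegerVector topo, IntegerVector absorb,
                              int nc) {
  const R_xlen_t ne1 = e1_from.size(), ne2 = e2_from.size();

  std::vector<double> v1(n1, 0.0);
  v1[p0] = 1.0;

  if (T > 0.0) {
    std::vector<double> rate1(ne1), out1(n1, 0.0);
    for (R_xlen_t e = 0; e < ne1; ++e) {
      rate1[e] = base1[e1_type[e] - 1] * e1_mult[e];
      out1[e1_from[e]] += rate1[e];
    }
    double lambda = 0.0;
    for (int i = 0; i < n1; ++i) lambda = std::max(lambda, out1[i]);
    if (lambda > 0.0) {
      int steps = (int)std::ceil(lambda * T / 100.0);
      if (steps < 1) steps = 1;
      double tau = T / steps;
      for (int s = 0; s < steps; ++s) {
        expm_dist(v1, INTEGER(e1_from), INTEGER(e1_to), rate1.data(), ne1,
                  out1, lambda, tau);
        Rcpp::checkUserInterrupt();
      }
    }
  }

  // project onto the single-deme phase at time T
  std::vector<double> v2(n2, 0.0);
  for (int i = 0; i < n1; ++i)
    if (v1[i] != 0.0) v2[proj[i]] += v1[i];

  std::vector<double> rate2(ne2), out2(n2, 0.0);
  for (R_xlen_t e = 0; e < ne2; ++e) {
    rate2[e] = base2[e2_type[e] - 1] * e2_mult[e];
    out2[e2_from[e]] += rate2[e];
  }

  NumericVector res(nc);
  // mass already absorbed (fully coalesced before T)
  for (int i = 0; i < n2; ++i)
    if (absorb[i] >= 0 && v2[i] != 0.0) res[absorb[i]] += v2[i];

  // transitions strictly coarsen the genealogy or increase counts, so a single
  // sweep in topological order yields the absorption distribution
  for (R_xlen_t k = 0; k < topo.size(); ++k) {
    const int s = topo[k];
    const double mass = v2[s];
    if (mass <= 0.0) continue;
    const double tot = out2[s];
    for (int e = e2_ptr[s]; e < e2_ptr[s + 1]; ++e) {
      const double q = mass * rate2[e] / tot;
      const int t = e2_to[e];
      if (absorb[t] >= 0) res[absorb[t]] += q; else v2[t] += q;
    }
    v2[s] = 0.0;
  }
  return res;
}
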
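#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Exact bSFS probabilities for one diploid sampled from each of two
// populations, under a two-epoch demography (structured phase with optional
// unidirectional backwards migration, then a single ancestral deme).
//
// The chain lives on (lineage configuration) x (truncated mutation-count
// vector).  Lineage configurations and their transitions are enumerated in R
// (lumped under the within-individual leaf-exchange symmetry) and passed in
// as edge lists; mutation events increment one of the four count coordinates
// (hetA, hetB, hetAB, fixed) determined by the leaves a lineage subtends.
// Counts are truncated at kmax: each coordinate has levels 0..kmax plus one
// marginal ">kmax" level into which further mutations are absorbed (they
// leave the state unchanged, so the corresponding rate is simply inactive).
//
// Phase 1 (before the split time, backwards) is integrated by uniformization,
// matrix-free.  Phase 2 is an absorbing chain; because counts only increase
// and coalescence strictly reduces the number of lineages, the absorption
// distribution is obtained by a single back-substitution sweep in
// topological order.

static inline int levelOf(int c, int stride, int L) {
  return (c / stride) % L;
}

// [[Rcpp::export]]
NumericVector bsfs_core_cpp(
    int ns1,
    IntegerVector e1from, IntegerVector e1to, IntegerVector e1cls,
    NumericVector e1mult,
    IntegerMatrix mut1,       // ns1 x 4 lineage-type multiplicities
    IntegerVector map12,      // phase1 state -> phase2 state (0-based)
    int s0,                   // initial phase-1 state (0-based)
    int ns2, int abs2,
    IntegerVector e2from, IntegerVector e2to, NumericVector e2mult,
    IntegerMatrix mut2,
    IntegerVector ord2,       // transient phase-2 states, decreasing lineage count
    double coalA, double coalB, double mig, double coalAnc,
    double mutRate, double Tgen, int kmax) {

  const int L = kmax + 2;
  const int C = L * L * L * L;
  const int stride[4] = {1, L, L * L, L * L * L};
  const int ne1 = e1from.size();
  const int ne2 = e2from.size();

  // phase-1 numeric rates
  std::vector<double> rate1(ne1);
  std::vector<double> gOut(ns1, 0.0);
  for (int e = 0; e < ne1; ++e) {
    double r = (e1cls[e] == 0) ? coalA : (e1cls[e] == 1 ? coalB : mig);
    rate1[e] = e1mult[e] * r;
    gOut[e1from[e]] += rate1[e];
  }
  std::vector<double> mutR1(ns1 * 4);
  std::vector<double> mutTot1(ns1, 0.0);
  for (int g = 0; g < ns1; ++g)
    for (int t = 0; t < 4; ++t) {
      mutR1[g * 4 + t] = mut1(g, t) * mutRate;
      mutTot1[g] += mutR1[g * 4 + t];
    }

  const int N1 = ns1 * C;
  std::vector<double> v(N1, 0.0);
  v[(size_t)s0 * C] = 1.0;

  double Lambda = 0.0;
  for (int g = 0; g < ns1; ++g)
    Lambda = std::max(Lambda, gOut[g] + mutTot1[g]);

  if (Tgen > 0 && Lambda > 0) {
    // split [0, T] so each uniformization step has a = Lambda*tau <= 25
    int nstep = (int)std::ceil(Lambda * Tgen / 25.0);
    if (nstep < 1) nstep = 1;
    double tau = Tgen / nstep;
    double a = Lambda * tau;
    std::vector<double> u(N1), qv(N1), acc(N1);
    for (int step = 0; step < nstep; ++step) {
      double w = std::exp(-a);
      for (int i = 0; i < N1; ++i) {
        u[i] = v[i];
        acc[i] = w * v[i];
      }
      for (int k = 1; k <= 100000; ++k) {
        // qv = Q^T u (probability flow)
        std::fill(qv.begin(), qv.end(), 0.0);
        for (int e = 0; e < ne1; ++e) {
          double re = rate1[e];
          if (re == 0) continue;
          const size_t bf = (size_t)e1from[e] * C, bt = (size_t)e1to[e] * C;
          for (int c = 0; c < C; ++c) {
            double m = re * u[bf + c];
            qv[bt + c] += m;
            qv[bf + c] -= m;
          }
        }
        for (int g = 0; g < ns1; ++g) {
          const size_t bg = (size_t)g * C;
          for (int t = 0; t < 4; ++t) {
            double r = mutR1[g * 4 + t];
            if (r == 0) continue;
            const int st = stride[t], blk = st * L;
            for (int hi = 0; hi < C / blk; ++hi)
              for (int lev = 0; lev < L - 1; ++lev) {
                const size_t base = bg + (size_t)hi * blk + (size_t)lev * st;
                for (int lo = 0; lo < st; ++lo) {
                  double m = r * u[base + lo];
                  qv[base + lo + st] += m;
                  qv[base + lo] -= m;
                }
              }
          }
        }
        double wnext = w * a / k;
        for (int i = 0; i < N1; ++i) {
          u[i] += qv[i] / Lambda;
          acc[i] += wnext * u[i];
        }
        w = wnext;
        if (k >= a && w < 1e-16) break;
      }
      v.swap(acc);
    }
  }

  // project onto phase-2 configurations
  const int N2 = ns2 * C;
  std::vector<double> inf(N2, 0.0);
  for (int g = 0; g < ns1; ++g) {
    const size_t bf = (size_t)g * C, bt = (size_t)map12[g] * C;
    for (int c = 0; c < C; ++c) inf[bt + c] += v[bf + c];
  }

  // phase-2 rates and adjacency
  std::vector<double> gOut2(ns2, 0.0);
  std::vector<std::vector<std::pair<int, double> > > adj(ns2);
  for (int e = 0; e < ne2; ++e) {
    double r = e2mult[e] * coalAnc;
    gOut2[e2from[e]] += r;
    adj[e2from[e]].push_back(std::make_pair((int)e2to[e], r));
  }
  std::vector<double> mutR2(ns2 * 4);
  for (int g = 0; g < ns2; ++g)
    for (int t = 0; t < 4; ++t) mutR2[g * 4 + t] = mut2(g, t) * mutRate;

  NumericVector pabs(C);
  const int nt2 = ord2.size();
  // counts only increase => increasing linear index is a topological order
  for (int c = 0; c < C; ++c) {
    int lev[4];
    for (int t = 0; t < 4; ++t) lev[t] = levelOf(c, stride[t], L);
    for (int o = 0; o < nt2; ++o) {
      const int g = ord2[o];
      double out = gOut2[g];
      for (int t = 0; t < 4; ++t)
        if (lev[t] < L - 1) out += mutR2[g * 4 + t];
      double mass = inf[(size_t)g * C + c];
      if (mass <= 0 || out <= 0) continue;
      double y = mass / out;  // expected occupation time
      for (size_t j = 0; j < adj[g].size(); ++j) {
        int h = adj[g][j].first;
        double flow = adj[g][j].second * y;
        if (h == abs2) pabs[c] += flow;
        else inf[(size_t)h * C + c] += flow;
      }
      for (int t = 0; t < 4; ++t)
        if (lev[t] < L - 1 && mutR2[g * 4 + t] > 0)
          inf[(size_t)g * C + c + stride[t]] += mutR2[g * 4 + t] * y;
    }
    pabs[c] += inf[(size_t)abs2 * C + c];
  }
  return pabs;
}
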
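#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Structured-coalescent simulator for one 256-bp-style pair-block: four
// lineages (two per diploid), two demes until Tgen (backwards), then one
// ancestral deme.  Mutations are laid down afterwards as Poisson draws on the
// per-type branch-length exposures (exact thinning of the mutation process),
// classified by the subtended-leaf rule.  Returns raw (untruncated) counts
// of hetA, hetB, hetAB, fixed per block.  Uses R's RNG, so determinism is
// governed by set.seed() in the caller.

// mutation type per lineage mask (bits a1=1,a2=2,b1=4,b2=8):
// 1=hetA 2=hetB 3=hetAB 4=fixed, 0 = invisible (MRCA)
static const int MASK_TYPE[16] = {0, 1, 1, 4, 2, 3, 3, 2,
                                  2, 3, 3, 2, 4, 1, 1, 0};

// [[Rcpp::export]]
IntegerMatrix simulate_blocks_cpp(int n, double NeA, double NeB, double NeAnc,
                                  double Tgen, double me, bool destA,
                                  double mu, int blockSites) {
  IntegerMatrix out(n, 4);
  const double rA = 1.0 / (2.0 * NeA);
  const double rB = 1.0 / (2.0 * NeB);
  const double rAnc = 1.0 / (2.0 * NeAnc);
  const double siteRate = mu * (double)blockSites;

  for (int b = 0; b < n; ++b) {
    int mask[4] = {1, 2, 4, 8};
    int deme[4] = {0, 0, 1, 1};  // 0 = A, 1 = B
    int k = 4;
    double E[4] = {0.0, 0.0, 0.0, 0.0};
    double t = 0.0;

    // phase 1: two demes, until Tgen
    while (k > 1 && t < Tgen) {
      int nA = 0;
      for (int i = 0; i < k; ++i)
        if (deme[i] == 0) ++nA;
      int nB = k - nA;
      double crA = rA * nA * (nA - 1) / 2.0;
      double crB = rB * nB * (nB - 1) / 2.0;
      double mr = me * (destA ? nA : nB);
      double tot = crA + crB + mr;
      double dt = (tot > 0) ? R::rexp(1.0 / tot) : R_PosInf;
      double rem = Tgen - t;
      double step = std::min(dt, rem);
      for (int i = 0; i < k; ++i) {
        int ty = MASK_TYPE[mask[i]];
        if (ty) E[ty - 1] += step;
      }
      t += step;
      if (dt >= rem) break;  // no event before Tgen
      double u = unif_rand() * tot;
      if (u < crA + crB) {
        int dm = (u < crA) ? 0 : 1;
        int nd = dm == 0 ? nA : nB;
        // pick an unordered pair within deme dm
        int pr = (int)std::floor(unif_rand() * (nd * (nd - 1) / 2.0));
        if (pr >= nd * (nd - 1) / 2) pr = nd * (nd - 1) / 2 - 1;
        int i1 = -1, i2 = -1, seen = 0;
        for (int i = 0; i < k && i1 < 0; ++i) {
          if (deme[i] != dm) continue;
          for (int j = i + 1; j < k; ++j) {
            if (deme[j] != dm) continue;
            if (seen == pr) { i1 = i; i2 = j; break; }
            ++seen;
          }
        }
        mask[i1] |= mask[i2];
        mask[i2] = mask[k - 1];
        deme[i2] = deme[k - 1];
        --k;
      } else {
        // migration: a lineage in the destination deme jumps to the source
        int dm = destA ? 0 : 1;
        int nd = destA ? nA : nB;
        int pick = (int)std::floor(unif_rand() * nd);
        if (pick >= nd) pick = nd - 1;
        for (int i = 0, seen = 0; i < k; ++i) {
          if (deme[i] != dm) continue;
          if (seen == pick) { deme[i] = 1 - dm; break; }
          ++seen;
        }
      }
    }

    // phase 2: one ancestral deme
    while (k > 1) {
      double tot = rAnc * k * (k - 1) / 2.0;
      double dt = R::rexp(1.0 / tot);
      for (int i = 0; i < k; ++i) {
        int ty = MASK_TYPE[mask[i]];
        if (ty) E[ty - 1] += dt;
      }
      int pr = (int)std::floor(unif_rand() * (k * (k - 1) / 2.0));
      if (pr >= k * (k - 1) / 2) pr = k * (k - 1) / 2 - 1;
      int i1 = -1, i2 = -1, seen = 0;
      for (int i = 0; i < k && i1 < 0; ++i)
        for (int j = i + 1; j < k; ++j) {
          if (seen == pr) { i1 = i; i2 = j; break; }
          ++seen;
        }
      mask[i1] |= mask[i2];
      mask[i2] = mask[k - 1];
      deme[i2] = deme[k - 1];
      --k;
    }

    for (int ty = 0; ty < 4; ++ty)
      out(b, ty) = (int)R::rpois(siteRate * E[ty]);
  }
  return out;
}
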
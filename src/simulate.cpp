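#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// branch-type class of a lineage subtending leaf set `mask`
// (bits 0,1 = haplotypes of the A individual; bits 2,3 = B individual):
// 0 invisible (root), 1 hetA, 2 hetB, 3 hetAB, 4 fixed difference
static int leaf_class4(unsigned mask) {
  int nA = ((mask >> 0) & 1) + ((mask >> 1) & 1);
  int nB = ((mask >> 2) & 1) + ((mask >> 3) & 1);
  if (nA == 2 && nB == 2) return 0;
  if (nA == 1 && nB == 1) return 3;
  if (nA == 1) return 1;
  if (nB == 1) return 2;
  return 4; // (2,0) or (0,2)
}

// Monte-Carlo simulation of the four-lineage structured coalescent used as the
// independent check of the matrix-exponential engine and as the fast
// unlinked-block simulator.  Returns an n_reps x 4 matrix of total branch
// lengths (scaled time) in the classes (hetA, hetB, hetAB, fixed).
// Rates are per scaled time unit: coalA/coalB per pair within demes A/B,
// migBA per lineage currently in B (backwards B->A), migAB the reverse,
// coalAnc per pair in the ancestral population entered at scaled time T.
// [[Rcpp::export]]
NumericMatrix sim_pair_lengths_cpp(int n_reps, double coalA, double coalB,
                                   double migBA, double migAB, double T,
                                   double coalAnc) {
  NumericMatrix out(n_reps, 4);
  for (int rep = 0; rep < n_reps; ++rep) {
    unsigned mask[4] = {1u, 2u, 4u, 8u};
    int loc[4] = {0, 0, 1, 1};
    int nlin = 4;
    double t = 0.0;
    double L[4] = {0.0, 0.0, 0.0, 0.0};

    // migration phase, duration T
    while (t < T) {
      int nA = 0, nB = 0;
      for (int i = 0; i < nlin; ++i) (loc[i] == 0 ? nA : nB)++;
      double rcA = coalA * nA * (nA - 1) / 2.0;
      double rcB = coalB * nB * (nB - 1) / 2.0;
      double rm = migBA * nB + migAB * nA;
      double rtot = rcA + rcB + rm;
      double dt = (rtot > 0.0) ? R::rexp(1.0 / rtot) : R_PosInf;
      double step = std::min(dt, T - t);
      for (int i = 0; i < nlin; ++i) {
        int c = leaf_class4(mask[i]);
        if (c) L[c - 1] += step;
      }
      if (!(dt < T - t)) { t = T; break; }
      t += dt;
      double u = R::unif_rand() * rtot;
      bool done = false;
      // coalescence within A, then B
      for (int d = 0; d < 2 && !done; ++d) {
        double cr = (d == 0) ? coalA : coalB;
        for (int i = 0; i < nlin - 1 && !done; ++i) {
          if (loc[i] != d) continue;
          for (int j = i + 1; j < nlin && !done; ++j) {
            if (loc[j] != d) continue;
            u -= cr;
            if (u < 0) {
              mask[i] |= mask[j];
              mask[j] = mask[nlin - 1];
              loc[j] = loc[nlin - 1];
              --nlin;
              done = true;
            }
          }
        }
      }
      // migration
      for (int i = 0; i < nlin && !done; ++i) {
        double mr = (loc[i] == 1) ? migBA : migAB;
        u -= mr;
        if (u < 0) { loc[i] = 1 - loc[i]; done = true; }
      }
      if (nlin == 1) { // fully coalesced before T: only invisible branch left
        t = T;
        break;
      }
    }

    // ancestral phase to absorption
    while (nlin > 1) {
      double rate = coalAnc * nlin * (nlin - 1) / 2.0;
      double dt = R::rexp(1.0 / rate);
      for (int i = 0; i < nlin; ++i) {
        int c = leaf_class4(mask[i]);
        if (c) L[c - 1] += dt;
      }
      int np = nlin * (nlin - 1) / 2;
      int pick = (int)(R::unif_rand() * np);
      if (pick >= np) pick = np - 1;
      int idx = 0, pi = 0, pj = 1;
      for (int i = 0; i < nlin - 1; ++i)
        for (int j = i + 1; j < nlin; ++j, ++idx)
          if (idx == pick) { pi = i; pj = j; }
      mask[pi] |= mask[pj];
      mask[pj] = mask[nlin - 1];
      --nlin;
    }
    for (int c = 0; c < 4; ++c) out(rep, c) = L[c];
  }
  return out;
}

// General n-lineage two-deme IM coalescent for whole-dataset simulation.
// Simulates n_blocks independent blocks of block_length sites for nA_dip + nB_dip
// diploids and drops infinite-sites mutations (theta_half = per-lineage
// per-block mutation rate in scaled time).  Returns per-mutation block index
// (0-based), site offset within the block (0-based) and a dosage matrix over
// diploid individuals (A individuals first).
// [[Rcpp::export]]
List sim_blocks_cpp(int n_blocks, int block_length, int nA_dip, int nB_dip,
                    double coalA, double coalB, double migBA, double migAB,
                    double T, double coalAnc, double theta_half) {
  const int nh = 2 * (nA_dip + nB_dip);
  const int nind = nA_dip + nB_dip;
  if (nh > 64) stop("at most 32 diploids in total are supported");

  std::vector<int> m_block, m_site;
  std::vector<int> m_dos; // flat, nind per mutation
  std::vector<uint64_t> mask(nh);
  std::vector<int> loc(nh);
  std::vector<char> used(block_length);

  for (int b = 0; b < n_blocks; ++b) {
    int nlin = nh;
    for (int i = 0; i < nh; ++i) {
      mask[i] = ((uint64_t)1) << i;
      loc[i] = (i < 2 * nA_dip) ? 0 : 1;
    }
    std::fill(used.begin(), used.end(), 0);
    double t = 0.0;
    bool anc = (T <= 0.0);

    while (nlin > 1) {
      double rcA = 0, rcB = 0, rm = 0, rtot;
      if (!anc) {
        int nA = 0, nB = 0;
        for (int i = 0; i < nlin; ++i) (loc[i] == 0 ? nA : nB)++;
        rcA = coalA * nA * (nA - 1) / 2.0;
        rcB = coalB * nB * (nB - 1) / 2.0;
        rm = migBA * nB + migAB * nA;
        rtot = rcA + rcB + rm;
      } else {
        rtot = coalAnc * nlin * (nlin - 1) / 2.0;
      }
      double dt = (rtot > 0.0) ? R::rexp(1.0 / rtot) : R_PosInf;
      double step = anc ? dt : std::min(dt, T - t);

      // mutations during this interval, uniformly over lineages
      if (theta_half > 0.0 && step > 0.0 && R_FINITE(step)) {
        int nm = (int)R::rpois(theta_half * nlin * step);
        for (int m = 0; m < nm; ++m) {
          int li = (int)(R::unif_rand() * nlin);
          if (li >= nlin) li = nlin - 1;
          int site = (int)(R::unif_rand() * block_length);
          if (site >= block_length) site = block_length - 1;
          if (used[site]) continue; // infinite sites: drop rare collisions
          uint64_t mk = mask[li];
          int pc = __builtin_popcountll(mk);
          if (pc == 0 || pc == nh) continue; // invisible
          used[site] = 1;
          m_block.push_back(b);
          m_site.push_back(site);
          for (int d = 0; d < nind; ++d) {
            int dos = (int)((mk >> (2 * d)) & 1) + (int)((mk >> (2 * d + 1)) & 1);
            m_dos.push_back(dos);
          }
        }
      }

      if (!anc) {
        if (!(dt < T - t)) { anc = true; t = T; continue; }
        t += dt;
        double u = R::unif_rand() * rtot;
        bool done = false;
        for (int d = 0; d < 2 && !done; ++d) {
          double cr = (d == 0) ? coalA : coalB;
          if (cr <= 0) continue;
          for (int i = 0; i < nlin - 1 && !done; ++i) {
            if (loc[i] != d) continue;
            for (int j = i + 1; j < nlin && !done; ++j) {
              if (loc[j] != d) continue;
              u -= cr;
              if (u < 0) {
                mask[i] |= mask[j];
                mask[j] = mask[nlin - 1];
                loc[j] = loc[nlin - 1];
                --nlin;
                done = true;
              }
            }
          }
        }
        for (int i = 0; i < nlin && !done; ++i) {
          double mr = (loc[i] == 1) ? migBA : migAB;
          if (mr <= 0) continue;
          u -= mr;
          if (u < 0) { loc[i] = 1 - loc[i]; done = true; }
        }
      } else {
        int np = nlin * (nlin - 1) / 2;
        int pick = (int)(R::unif_rand() * np);
        if (pick >= np) pick = np - 1;
        int idx = 0, pi = 0, pj = 1;
        for (int i = 0; i < nlin - 1; ++i)
          for (int j = i + 1; j < nlin; ++j, ++idx)
            if (idx == pick) { pi = i; pj = j; }
        mask[pi] |= mask[pj];
        mask[pj] = mask[nlin - 1];
        --nlin;
      }
    }
    if (b % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  const int nm = (int)m_block.size();
  IntegerMatrix dos(nm, nind);
  for (int m = 0; m < nm; ++m)
    for (int d = 0; d < nind; ++d) dos(m, d) = m_dos[(size_t)m * nind + d];
  return List::create(_["block"] = wrap(m_block), _["site"] = wrap(m_site),
                      _["dosage"] = dos);
}
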
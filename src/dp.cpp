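#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Base codes: A=0, C=1, G=2, U=3.
// Pair classes: 0 = none, 1 = Watson-Crick-Franklin, 2 = G:U wobble.
static inline int pclass(int a, int b) {
  if ((a == 0 && b == 3) || (a == 3 && b == 0) ||
      (a == 1 && b == 2) || (a == 2 && b == 1)) return 1;
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 2;
  return 0;
}

// lexicographic preference: higher score, then smaller |offset|,
// then fewer interruption events
static inline bool better(double s1, int a1, int n1,
                          double s2, int a2, int n2) {
  const double eps = 1e-9;
  if (s1 > s2 + eps) return true;
  if (s1 < s2 - eps) return false;
  if (a1 != a2) return a1 < a2;
  return n1 < n2;
}

// Optimal 3'-pairing configuration between miRNA positions >= p0 (1-based)
// and a target window (codes in window orientation 5'->3', index 0-based).
// Antiparallel geometry: miRNA position increases as window index decreases.
// The window is anchored so that its 3' edge (index W-1) sits one nucleotide
// 5' of the target base opposite miRNA position 8; the target-side loop of a
// pair at window index j is therefore (W-1-j) and the miRNA-side loop of a
// pair at miRNA position i is (i-9).
// [[Rcpp::export]]
List dp_best_config(IntegerVector mir, IntegerVector win, int p0,
                    double match_point, double end_bonus, double term_wobble,
                    double interruption_point, double offset_point,
                    int offset_free) {
  const int L = mir.size();
  const int W = win.size();
  List empty = List::create(_["score"] = 0.0,
                            _["mirna_pos"] = IntegerVector(0),
                            _["win_idx"] = IntegerVector(0),
                            _["pair_class"] = IntegerVector(0),
                            _["offset"] = NA_INTEGER,
                            _["n_interruptions"] = 0);
  if (W <= 0 || p0 > L) return empty;

  const int NI = L - p0 + 1;              // candidate miRNA positions
  const int NC = NI * W;                  // cells, keyed (i, j)
  std::vector<double> S(NC, R_NegInf);    // best chain score ending at cell
  std::vector<int> AO(NC, 0);             // |offset| of that chain
  std::vector<int> SO(NC, 0);             // signed offset
  std::vector<int> NIN(NC, 0);            // interruption events
  std::vector<int> PAR(NC, -1);           // predecessor cell
  std::vector<int> CLS(NC, 0);            // pair class at cell

  auto cell = [&](int ii, int j) { return ii * W + j; };

  for (int i = p0; i <= L; ++i) {
    const int ii = i - p0;
    for (int j = 0; j < W; ++j) {
      const int cls = pclass(mir[i - 1], win[j]);
      if (cls == 0) continue;
      double ps = 0.0;
      if (cls == 1) {
        if (i > 12) ps += match_point;
        if (i == L - 1 || i == L - 2) ps += end_bonus;
      } else if (i == L) {
        ps += term_wobble;
      }
      const int tl = W - 1 - j;           // target-side loop if first pair
      const int ml = i - 9;               // miRNA-side loop if first pair
      const int off = tl - ml;
      const int aoff = off >= 0 ? off : -off;
      const double offpen =
          offset_point * (aoff > offset_free ? aoff - offset_free : 0);

      // start a new chain here
      double bs = ps - offpen;
      int bao = aoff, bso = off, bni = 0, bpar = -1;

      // or extend a chain whose previous pair is (k, l), k < i, l > j
      for (int k = p0; k < i; ++k) {
        const int kk = k - p0;
        for (int l = j + 1; l < W; ++l) {
          const int c = cell(kk, l);
          if (!R_FINITE(S[c])) continue;
          const int gm = i - k - 1, gt = l - j - 1;
          const int gap = gm > gt ? gm : gt;
          const double cand = S[c] + ps - interruption_point * gap;
          const int nin = NIN[c] + (gap > 0 ? 1 : 0);
          if (better(cand, AO[c], nin, bs, bao, bni)) {
            bs = cand; bao = AO[c]; bso = SO[c]; bni = nin; bpar = c;
          }
        }
      }
      const int me = cell(ii, j);
      S[me] = bs; AO[me] = bao; SO[me] = bso; NIN[me] = bni;
      PAR[me] = bpar; CLS[me] = cls;
    }
  }

  // pick the best terminal cell; empty configuration scores 0
  double bests = 0.0; int besta = 0, bestn = 0, bestc = -1, bestj = W;
  for (int ii = 0; ii < NI; ++ii) {
    for (int j = 0; j < W; ++j) {
      const int c = cell(ii, j);
      if (!R_FINITE(S[c])) continue;
      const bool gain = better(S[c], AO[c], NIN[c], bests, besta, bestn);
      const bool loss = better(bests, besta, bestn, S[c], AO[c], NIN[c]);
      if (gain || (!loss && bestc >= 0 && j < bestj)) {
        bests = S[c]; besta = AO[c]; bestn = NIN[c]; bestc = c; bestj = j;
      }
    }
  }
  if (bestc < 0 || bests <= 1e-9) return empty;

  std::vector<int> chain;
  for (int c = bestc; c >= 0; c = PAR[c]) chain.push_back(c);
  const int np = chain.size();
  IntegerVector mp(np), wj(np), pc(np);
  for (int r = 0; r < np; ++r) {          // chain is last -> first
    const int c = chain[np - 1 - r];
    mp[r] = c / W + p0;
    wj[r] = c % W;
    pc[r] = CLS[c];
  }
  return List::create(_["score"] = bests, _["mirna_pos"] = mp,
                      _["win_idx"] = wj, _["pair_class"] = pc,
                      _["offset"] = SO[bestc],
                      _["n_interruptions"] = NIN[bestc]);
}

// Intermolecular-only duplex minimum free energy under a reduced
// nearest-neighbor model. a and b are both 5'->3'; pair (i, j) means
// a[i] : b[j]; successive pairs have increasing i and decreasing j.
// stack is a 6x6 matrix over pair types AU, CG, GC, UA, GU, UG where
// stack[p, q] is the energy of stacking pair q 3' of pair p on strand a.
static inline int ptype(int a, int b) {
  if (a == 0 && b == 3) return 0;  // AU
  if (a == 1 && b == 2) return 1;  // CG
  if (a == 2 && b == 1) return 2;  // GC
  if (a == 3 && b == 0) return 3;  // UA
  if (a == 2 && b == 3) return 4;  // GU
  if (a == 3 && b == 2) return 5;  // UG
  return -1;
}

// [[Rcpp::export]]
List dp_duplex(IntegerVector a, IntegerVector b, NumericMatrix stack,
               double init, double term_au, double bulge_base,
               double bulge_ext, double il_base, double il_ext,
               double il_asym, int max_loop) {
  const int n = a.size(), m = b.size();
  List nod = List::create(_["energy"] = NA_REAL, _["i"] = IntegerVector(0),
                          _["j"] = IntegerVector(0), _["no_duplex"] = true);
  if (n == 0 || m == 0) return nod;

  std::vector<double> E((size_t)n * m, R_PosInf);
  std::vector<int> PAR((size_t)n * m, -1);
  auto cell = [&](int i, int j) { return (size_t)i * m + j; };
  auto endpen = [&](int pt) {
    return (pt == 0 || pt == 3 || pt == 4 || pt == 5) ? term_au : 0.0;
  };

  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      const int pt = ptype(a[i], b[j]);
      if (pt < 0) continue;
      double best = endpen(pt);            // open the duplex at (i, j)
      int par = -1;
      for (int k = std::max(0, i - 1 - max_loop); k < i; ++k) {
        for (int l = j + 1; l <= std::min(m - 1, j + 1 + max_loop); ++l) {
          const size_t c = cell(k, l);
          if (!R_FINITE(E[c])) continue;
          const int qt = ptype(a[k], b[l]);
          const int gm = i - k - 1, gt = l - j - 1;
          double loop;
          if (gm == 0 && gt == 0) {
            loop = stack(qt, pt);
          } else if (gm == 0 || gt == 0) {
            loop = bulge_base + bulge_ext * (std::max(gm, gt) - 1);
          } else {
            loop = il_base + il_ext * (gm + gt) + il_asym * std::abs(gm - gt);
          }
          if (E[c] + loop < best) { best = E[c] + loop; par = (int)c; }
        }
      }
      E[cell(i, j)] = best;
      PAR[cell(i, j)] = par;
    }
  }

  double mfe = R_PosInf; int bc = -1;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j) {
      const size_t c = cell(i, j);
      if (!R_FINITE(E[c])) continue;
      const double tot = init + E[c] + endpen(ptype(a[i], b[j]));
      if (tot < mfe) { mfe = tot; bc = (int)c; }
    }
  if (bc < 0 || mfe >= init - 1e-9) return nod;

  std::vector<int> chain;
  for (int c = bc; c >= 0; c = PAR[c]) chain.push_back(c);
  const int np = chain.size();
  IntegerVector pi(np), pj(np);
  for (int r = 0; r < np; ++r) {
    const int c = chain[np - 1 - r];
    pi[r] = c / m + 1;
    pj[r] = c % m + 1;
  }
  return List::create(_["energy"] = mfe, _["i"] = pi, _["j"] = pj,
                      _["no_duplex"] = false);
}
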
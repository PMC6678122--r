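#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Base coding used throughout: A=0, C=1, G=2, U/T=3.
// Pair types: AU=0, UA=1, GC=2, CG=3, GU=4, UG=5, unpairable=-1.
static inline int pair_index(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

// Watson-Crick pair type of a base against its exact complement.
static inline int wc_pair(int a) {
  switch (a) {
    case 0: return 0;  // A:U
    case 1: return 3;  // C:G
    case 2: return 2;  // G:C
    default: return 1; // U:A
  }
}

// Single-stem minimum-free-energy fold.
//
// Structures are chains of nested pairs (i1,j1) > (i2,j2) > ... > (ik,jk)
// with no multibranching: consecutive pairs either stack (contiguous) or are
// separated by a bulge/interior loop of at most `max_gap` unpaired bases per
// side; the innermost pair closes a terminal (hairpin) loop of at least
// `min_loop` bases. Energy = sum of stacking terms + linear loop penalties.
// The open chain scores 0, so the reported MFE is never positive.
//
// E(i,j) = best energy of a chain whose outermost pair is (i,j):
//   E(i,j) = min( hairpin_a + hairpin_b*(j-i-1),
//                 min_{(k,l) inside} E(k,l) + step(i,j,k,l) )
// step = stack table entry when contiguous, else loop_a + loop_b*(gap sizes).
// Ties broken deterministically: hairpin closure first, then smallest k,
// then largest l; outer pair by smallest i, then smallest j.
// [[Rcpp::export]]
List fold_engine(IntegerVector seq, NumericMatrix stack,
                 double hairpin_a, double hairpin_b,
                 double loop_a, double loop_b,
                 int min_loop, int max_gap) {
  int n = seq.size();
  const double INF = 1e9;
  std::vector<std::vector<double> > E(n, std::vector<double>(n, INF));
  std::vector<std::vector<int> > bk(n, std::vector<int>(n, -2));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pij = pair_index(seq[i], seq[j]);
      if (pij < 0) continue;
      double best = hairpin_a + hairpin_b * (j - i - 1);
      int bestkl = -1; // -1 = hairpin closure
      for (int k = i + 1; k <= i + 1 + max_gap && k < j; ++k) {
        for (int l = j - 1; l >= j - 1 - max_gap && l > k; --l) {
          if (l - k - 1 < min_loop) continue;
          if (E[k][l] >= INF) continue;
          int g1 = k - i - 1, g2 = j - l - 1;
          double step = (g1 == 0 && g2 == 0)
            ? stack(pij, pair_index(seq[k], seq[l]))
            : loop_a + loop_b * (g1 + g2);
          double e = E[k][l] + step;
          if (e < best - 1e-9) { best = e; bestkl = k * n + l; }
        }
      }
      E[i][j] = best;
      bk[i][j] = bestkl;
    }
  }
  double mfe = 0.0;
  int oi = -1, oj = -1;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (E[i][j] < mfe - 1e-9) { mfe = E[i][j]; oi = i; oj = j; }
  std::string db(n, '.');
  int npairs = 0;
  if (oi >= 0) {
    int i = oi, j = oj;
    while (true) {
      db[i] = '('; db[j] = ')'; ++npairs;
      int enc = bk[i][j];
      if (enc < 0) break;
      i = enc / n; j = enc % n;
    }
  }
  return List::create(_["structure"] = db, _["mfe"] = mfe,
                      _["n_pairs"] = npairs);
}

// Scan one unigene with one miRNA under the positional complementarity rules.
//
// The miRNA binds antiparallel: miRNA position k (1 = 5' end) pairs with
// window base L+1-k. Per-position penalty: WC match 0, G:U wobble 0.5,
// mismatch 1. A window passes iff
//   (1) total penalty <= max_score,
//   (2) no run of > max_adjacent consecutive full mismatches anywhere,
//   (3) no two adjacent full mismatches within positions 2..12,
//   (4) no full mismatch at positions 10-11 (G:U allowed iff gu_ok_1011),
//   (5) sum of penalties over positions 1..12 <= max_seed_score,
//   (6) duplex MFE >= min_ratio % of the perfect-complement duplex MFE.
// Duplex energies: duplex_init + stacking over runs of consecutive paired
// positions; mismatches interrupt stacking.
// Returns parallel vectors for passing windows only (1-based coordinates).
// [[Rcpp::export]]
List scan_engine(IntegerVector mir, IntegerVector uni, NumericMatrix stack,
                 double duplex_init, double max_score, double max_seed_score,
                 int max_adjacent, bool gu_ok_1011, double min_ratio) {
  int L = mir.size(), n = uni.size();
  std::vector<int> starts;
  std::vector<double> scores, dmfes, ratios;
  std::vector<std::string> pairings;
  // perfect-complement duplex energy for this miRNA
  double perfect = duplex_init;
  for (int k = 0; k + 1 < L; ++k)
    perfect += stack(wc_pair(mir[k]), wc_pair(mir[k + 1]));
  std::vector<int> ptype(L);
  for (int s = 0; s + L <= n; ++s) {
    double score = 0.0, seed = 0.0;
    int run = 0, maxrun = 0;
    bool fail = false;
    for (int k = 0; k < L; ++k) {
      int p = pair_index(mir[k], uni[s + L - 1 - k]);
      ptype[k] = p;
      int pos = k + 1;
      double pen = (p < 0) ? 1.0 : (p >= 4 ? 0.5 : 0.0);
      score += pen;
      if (pos <= 12) seed += pen;
      if (p < 0) {
        ++run;
        if (run > maxrun) maxrun = run;
        if (run >= 2 && pos >= 3 && pos <= 12) fail = true; // adjacent in 2..12
        if (pos == 10 || pos == 11) fail = true;
      } else {
        run = 0;
        if ((pos == 10 || pos == 11) && p >= 4 && !gu_ok_1011) fail = true;
      }
      if (score > max_score) { fail = true; break; }
    }
    if (fail || score > max_score || seed > max_seed_score ||
        maxrun > max_adjacent)
      continue;
    double dmfe = duplex_init;
    for (int k = 0; k + 1 < L; ++k)
      if (ptype[k] >= 0 && ptype[k + 1] >= 0)
        dmfe += stack(ptype[k], ptype[k + 1]);
    double ratio = 100.0 * dmfe / perfect;
    if (ratio < min_ratio) continue;
    std::string pr(L, '.');
    for (int k = 0; k < L; ++k)
      pr[k] = ptype[k] < 0 ? '.' : (ptype[k] >= 4 ? 'o' : '|');
    starts.push_back(s + 1);
    scores.push_back(score);
    dmfes.push_back(dmfe);
    ratios.push_back(ratio);
    pairings.push_back(pr);
  }
  return List::create(_["start"] = starts, _["score"] = scores,
                      _["duplex_mfe"] = dmfes, _["ratio"] = ratios,
                      _["pairing"] = pairings, _["perfect_mfe"] = perfect);
}
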
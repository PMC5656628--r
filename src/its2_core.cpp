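#include <Rcpp.h>
using namespace Rcpp;

// Base encoding used throughout: A=0, C=1, G=2, U=3, anything else (IUPAC
// ambiguity, gap) = -1 and can never pair.
static inline int pair_score_int(int a, int b, const int *w) {
  if (a < 0 || b < 0) return 0;
  // w = {AU, GC, GU} weights
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return w[0];
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return w[1];
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return w[2];
  return 0;
}

// Weighted-pair maximization (Nussinov recurrence) fill.
// enc: encoded sequence; weights: c(AU, GC, GU); min_loop: minimum number of
// unpaired nucleotides enclosed by a pair. Returns the (n x n) score matrix;
// traceback is done in R where candidate bookkeeping lives.
// [[Rcpp::export]]
IntegerMatrix nussinov_fill_cpp(IntegerVector enc, IntegerVector weights,
                                int min_loop) {
  int n = enc.size();
  int w[3] = {weights[0], weights[1], weights[2]};
  IntegerMatrix V(n, n);
  if (n == 0) return V;
  for (int l = 1; l < n; ++l) {
    for (int i = 0; i + l < n; ++i) {
      int j = i + l;
      int best = V(i, j - 1); // j unpaired
      // j paired with some k in [i, j - min_loop - 1]
      int kmax = j - min_loop - 1;
      for (int k = i; k <= kmax; ++k) {
        int s = pair_score_int(enc[k], enc[j], w);
        if (s == 0) continue;
        int cand = s + (k > i ? V(i, k - 1) : 0) + (k + 1 <= j - 1 ? V(k + 1, j - 1) : 0);
        if (cand > best) best = cand;
      }
      V(i, j) = best;
    }
  }
  return V;
}

// Global affine-gap (Gotoh) alignment over a precomputed column-score matrix
// S (n x m): S(i, j) is the score of aligning column i of x with column j of
// y. gap_open/gap_extend are <= 0; a gap of length L costs
// gap_open + L * gap_extend. Deterministic tie-break: diagonal, then up
// (gap in y, consuming x), then left.
// Returns a list(ai, bi) of equal-length integer vectors: 1-based indices
// into x and y, 0 for a gap.
// [[Rcpp::export]]
List affine_align_cpp(NumericMatrix S, double gap_open, double gap_extend) {
  int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;
  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  // state trace: 0 = M, 1 = Ix (up), 2 = Iy (left); one per matrix cell
  IntegerMatrix TM(n + 1, m + 1), TX(n + 1, m + 1), TY(n + 1, m + 1);
  M(0, 0) = 0; Ix(0, 0) = NEG; Iy(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Iy(i, 0) = NEG;
    Ix(i, 0) = gap_open + i * gap_extend;
    TX(i, 0) = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; Ix(0, j) = NEG;
    Iy(0, j) = gap_open + j * gap_extend;
    TY(0, j) = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: diagonal move from best of three states
      double a = M(i - 1, j - 1), b = Ix(i - 1, j - 1), c = Iy(i - 1, j - 1);
      int tb = 0; double best = a;
      if (b > best) { best = b; tb = 1; }
      if (c > best) { best = c; tb = 2; }
      M(i, j) = best + S(i - 1, j - 1);
      TM(i, j) = tb;
      // Ix: gap in y (consume x[i])
      double open_ = M(i - 1, j) + gap_open + gap_extend;
      double ext_ = Ix(i - 1, j) + gap_extend;
      if (open_ >= ext_) { Ix(i, j) = open_; TX(i, j) = 0; }
      else { Ix(i, j) = ext_; TX(i, j) = 1; }
      // Iy: gap in x (consume y[j]); disallow Ix -> Iy adjacency? standard
      // Gotoh allows it; keep standard, but prefer M on ties.
      double openy = M(i, j - 1) + gap_open + gap_extend;
      double exty = Iy(i, j - 1) + gap_extend;
      if (openy >= exty) { Iy(i, j) = openy; TY(i, j) = 0; }
      else { Iy(i, j) = exty; TY(i, j) = 2; }
    }
  }
  // terminal state: prefer M, then Ix, then Iy on ties
  int st = 0; double best = M(n, m);
  if (Ix(n, m) > best) { best = Ix(n, m); st = 1; }
  if (Iy(n, m) > best) { best = Iy(n, m); st = 2; }
  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (st == 0) {
      int prev = TM(i, j);
      ai.push_back(i); bi.push_back(j);
      --i; --j; st = prev;
    } else if (st == 1) {
      int prev = TX(i, j);
      ai.push_back(i); bi.push_back(0);
      --i; st = prev;
    } else {
      int prev = TY(i, j);
      ai.push_back(0); bi.push_back(j);
      --j; st = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());
  return List::create(_["ai"] = wrap(ai), _["bi"] = wrap(bi),
                      _["score"] = best);
}

// Exhaustive enumeration oracle: recursively decides the leftmost undecided
// position (unpaired, or paired with every admissible non-crossing partner),
// tracking the running score. Independent of the DP fill above. Guarded to
// short sequences by the R wrapper.
static void bf_rec(const std::vector<int> &enc, const int *w, int min_loop,
                   int pos, std::vector<int> &partner, int score,
                   int &best, std::vector<std::vector<int>> &best_structs) {
  int n = (int)enc.size();
  while (pos < n && partner[pos] != -2) ++pos; // -2 marks "undecided"
  if (pos >= n) {
    if (score > best) {
      best = score;
      best_structs.clear();
      best_structs.push_back(partner);
    } else if (score == best) {
      best_structs.push_back(partner);
    }
    return;
  }
  // leave pos unpaired
  partner[pos] = -1;
  bf_rec(enc, w, min_loop, pos + 1, partner, score, best, best_structs);
  partner[pos] = -2;
  // pair pos with k
  for (int k = pos + min_loop + 1; k < n; ++k) {
    if (partner[k] != -2) continue;
    int s = pair_score_int(enc[pos], enc[k], w);
    if (s == 0) continue;
    bool ok = true; // crossing check against decided pairs
    for (int t = 0; t < n && ok; ++t) {
      int p = partner[t];
      if (p >= 0 && p > t) {
        bool ia = t > pos && t < k;
        bool ib = p > pos && p < k;
        if (ia != ib) ok = false;
      }
    }
    if (!ok) continue;
    partner[pos] = k; partner[k] = pos;
    bf_rec(enc, w, min_loop, pos + 1, partner, score + s, best, best_structs);
    partner[pos] = -2; partner[k] = -2;
  }
}

// [[Rcpp::export]]
List brute_force_cpp(IntegerVector enc, IntegerVector weights, int min_loop) {
  int n = enc.size();
  int w[3] = {weights[0], weights[1], weights[2]};
  std::vector<int> e(enc.begin(), enc.end());
  std::vector<int> partner(n, -2);
  int best = -1;
  std::vector<std::vector<int>> best_structs;
  bf_rec(e, w, min_loop, 0, partner, 0, best, best_structs);
  std::vector<std::string> dbs;
  dbs.reserve(best_structs.size());
  for (auto &p : best_structs) {
    std::string s(n, '.');
    for (int i = 0; i < n; ++i) {
      if (p[i] >= 0) s[i] = (p[i] > i) ? '(' : ')';
    }
    dbs.push_back(s);
  }
  std::sort(dbs.begin(), dbs.end());
  dbs.erase(std::unique(dbs.begin(), dbs.end()), dbs.end());
  return List::create(_["score"] = best, _["structures"] = wrap(dbs));
}
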
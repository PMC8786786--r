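#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap global (Needleman-Wunsch) alignment.
//
// Gap cost for a run of length L is gap_open + L * gap_extend. With
// free_end_gaps (the EMBOSS-needle default) terminal gap runs cost
// nothing, which is the convention expected when comparing full-length
// gene sequences of different extents.
//
// Tie-breaking is deterministic: diagonal is preferred, then the
// vertical move (gap in b, consuming a), then the horizontal move.
//
// States: 0 = M (diagonal), 1 = X (gap in b, vertical), 2 = Y (gap in a,
// horizontal).
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, double match,
                  double mismatch, double gap_open, double gap_extend,
                  bool free_end_gaps) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  const double open1 = gap_open + gap_extend;  // opening a 1-long gap
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
  std::vector<double> M((size_t)(n + 1) * (m + 1), NEG);
  std::vector<double> X(M), Y(M);
  std::vector<signed char> pM(M.size(), -1), pX(M.size(), -1), pY(M.size(), -1);

  M[idx(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[idx(i, 0)] = free_end_gaps ? 0.0 : -(gap_open + i * gap_extend);
    pX[idx(i, 0)] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[idx(0, j)] = free_end_gaps ? 0.0 : -(gap_open + j * gap_extend);
    pY[idx(0, j)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = idx(i, j);
      // diagonal
      {
        const size_t d = idx(i - 1, j - 1);
        double best = M[d]; signed char st = 0;
        if (X[d] > best) { best = X[d]; st = 1; }
        if (Y[d] > best) { best = Y[d]; st = 2; }
        const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
        M[c] = best + s; pM[c] = st;
      }
      // vertical: gap in b, consuming a[i]; free in the last column
      {
        const bool term = free_end_gaps && j == m;
        const double co = term ? 0.0 : open1, ce = term ? 0.0 : gap_extend;
        const size_t u = idx(i - 1, j);
        double best = M[u] - co; signed char st = 0;
        if (X[u] - ce > best) { best = X[u] - ce; st = 1; }
        if (Y[u] - co > best) { best = Y[u] - co; st = 2; }
        X[c] = best; pX[c] = st;
      }
      // horizontal: gap in a, consuming b[j]; free in the last row
      {
        const bool term = free_end_gaps && i == n;
        const double co = term ? 0.0 : open1, ce = term ? 0.0 : gap_extend;
        const size_t l = idx(i, j - 1);
        double best = M[l] - co; signed char st = 0;
        if (X[l] - co > best) { best = X[l] - co; st = 1; }
        if (Y[l] - ce > best) { best = Y[l] - ce; st = 2; }
        Y[c] = best; pY[c] = st;
      }
    }
  }

  const size_t end = idx(n, m);
  double score = M[end]; int state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  // traceback
  std::string ga, gb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i == 0) state = 2;
    else if (j == 0) state = 1;
    if (state == 0) {
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      state = pM[idx(i, j)]; --i; --j;
    } else if (state == 1) {
      ga.push_back(a[i - 1]); gb.push_back('-');
      state = pX[idx(i, j)]; --i;
    } else {
      ga.push_back('-'); gb.push_back(b[j - 1]);
      state = pY[idx(i, j)]; --j;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["gapped_a"] = ga, _["gapped_b"] = gb,
                      _["score"] = score);
}
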
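#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment (Needleman-Wunsch with affine gaps, Gotoh
// three-state recursion). A gap of length L costs gap_open + L * gap_extend
// (both negative). Returns the number of identical columns and the total
// alignment length of one optimal alignment, for identity computation.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List nw_align_stats(std::string a, std::string b, double match,
                    double mismatch, double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");

  // state 0 = M (a[i] ~ b[j]), 1 = X (gap in b), 2 = Y (gap in a)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  // traceback: which predecessor state fed each cell's state
  std::vector<signed char> tbM((n + 1) * (m + 1), -1);
  std::vector<signed char> tbX((n + 1) * (m + 1), -1);
  std::vector<signed char> tbY((n + 1) * (m + 1), -1);
  const int W = m + 1;

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = gap_open + gap_extend * i;
    tbX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + gap_extend * j;
    tbY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1);
      const int u = (i - 1) * W + j, l = i * W + (j - 1);
      // M: diagonal move
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double best = M[d]; signed char arg = 0;
      if (X[d] > best) { best = X[d]; arg = 1; }
      if (Y[d] > best) { best = Y[d]; arg = 2; }
      if (best > NEG_INF) { M[c] = best + s; tbM[c] = arg; }
      // X: consume a[i-1] against a gap
      double xo = (M[u] > Y[u] ? M[u] : Y[u]) + gap_open + gap_extend;
      double xe = X[u] + gap_extend;
      if (xo >= xe) { X[c] = xo; tbX[c] = (M[u] >= Y[u]) ? 0 : 2; }
      else          { X[c] = xe; tbX[c] = 1; }
      // Y: consume b[j-1] against a gap
      double yo = (M[l] > X[l] ? M[l] : X[l]) + gap_open + gap_extend;
      double ye = Y[l] + gap_extend;
      if (yo >= ye) { Y[c] = yo; tbY[c] = (M[l] >= X[l]) ? 0 : 1; }
      else          { Y[c] = ye; tbY[c] = 2; }
    }
  }

  const int end = n * W + m;
  int state = 0; double score = M[end];
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  int i = n, j = m, matches = 0, cols = 0;
  while (i > 0 || j > 0) {
    ++cols;
    int c = i * W + j;
    if (state == 0) {
      if (a[i - 1] == b[j - 1]) ++matches;
      state = tbM[c]; --i; --j;
    } else if (state == 1) {
      state = tbX[c]; --i;
    } else {
      state = tbY[c]; --j;
    }
  }

  return List::create(_["score"] = score, _["matches"] = matches,
                      _["align_length"] = cols);
}
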
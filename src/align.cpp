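#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Global pairwise alignment with affine gaps (Gotoh three-state DP).
// Gap of length L costs gap_open + (L - 1) * gap_extend, i.e. entering a
// gap state pays gap_open for its first position and gap_extend for each
// further one. Traceback is deterministic: on ties the diagonal (match)
// state wins over the up state (gap in b) which wins over the left state
// (gap in a), both when choosing the cell state and when choosing the
// predecessor within a gap state.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export]]
List align_pair_cpp(std::string a, std::string b,
                    double match = 1.0, double mismatch = -1.0,
                    double gap_open = -5.0, double gap_extend = -1.0) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("align_pair_cpp: empty sequence");

  std::vector<std::vector<double>> M(n + 1, std::vector<double>(m + 1, NEG_INF));
  std::vector<std::vector<double>> X(n + 1, std::vector<double>(m + 1, NEG_INF)); // gap in b (consumes a)
  std::vector<std::vector<double>> Y(n + 1, std::vector<double>(m + 1, NEG_INF)); // gap in a (consumes b)
  // predecessor state per cell/state: 0 = M, 1 = X, 2 = Y
  std::vector<std::vector<char>> pM(n + 1, std::vector<char>(m + 1, 0));
  std::vector<std::vector<char>> pX(n + 1, std::vector<char>(m + 1, 0));
  std::vector<std::vector<char>> pY(n + 1, std::vector<char>(m + 1, 0));

  M[0][0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i][0] = gap_open + (i - 1) * gap_extend;
    pX[i][0] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[0][j] = gap_open + (j - 1) * gap_extend;
    pY[0][j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M: diagonal from the best of the three states (priority M > X > Y)
      double best = M[i - 1][j - 1];
      char st = 0;
      if (X[i - 1][j - 1] > best) { best = X[i - 1][j - 1]; st = 1; }
      if (Y[i - 1][j - 1] > best) { best = Y[i - 1][j - 1]; st = 2; }
      if (best > NEG_INF) { M[i][j] = best + s; pM[i][j] = st; }

      // X: gap in b, consuming a[i-1]; extending X costs gap_extend
      double vm = (M[i - 1][j] > NEG_INF) ? M[i - 1][j] + gap_open : NEG_INF;
      double vx = (X[i - 1][j] > NEG_INF) ? X[i - 1][j] + gap_extend : NEG_INF;
      double vy = (Y[i - 1][j] > NEG_INF) ? Y[i - 1][j] + gap_open : NEG_INF;
      best = vm; st = 0;
      if (vx > best) { best = vx; st = 1; }
      if (vy > best) { best = vy; st = 2; }
      if (best > NEG_INF) { X[i][j] = best; pX[i][j] = st; }

      // Y: gap in a, consuming b[j-1]
      vm = (M[i][j - 1] > NEG_INF) ? M[i][j - 1] + gap_open : NEG_INF;
      vx = (X[i][j - 1] > NEG_INF) ? X[i][j - 1] + gap_open : NEG_INF;
      vy = (Y[i][j - 1] > NEG_INF) ? Y[i][j - 1] + gap_extend : NEG_INF;
      best = vm; st = 0;
      if (vx > best) { best = vx; st = 1; }
      if (vy > best) { best = vy; st = 2; }
      if (best > NEG_INF) { Y[i][j] = best; pY[i][j] = st; }
    }
  }

  double score = M[n][m];
  char state = 0;
  if (X[n][m] > score) { score = X[n][m]; state = 1; }
  if (Y[n][m] > score) { score = Y[n][m]; state = 2; }

  std::string aa, bb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      char prev = pM[i][j];
      aa.push_back(a[i - 1]);
      bb.push_back(b[j - 1]);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      char prev = pX[i][j];
      aa.push_back(a[i - 1]);
      bb.push_back('-');
      --i;
      state = prev;
    } else {
      char prev = pY[i][j];
      aa.push_back('-');
      bb.push_back(b[j - 1]);
      --j;
      state = prev;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["aligned_a"] = aa, _["aligned_b"] = bb,
                      _["score"] = score);
}
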
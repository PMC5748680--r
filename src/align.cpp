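// Affine-gap pairwise alignment (Gotoh three-state DP) with deterministic
// traceback: ties resolved diagonal > up (gap in b) > left (gap in a).
// A gap of length L costs gap_open + L * gap_extend.
#include <Rcpp.h>
#include <limits>
#include <string>
#include <vector>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// state codes: 0 = M (diagonal), 1 = X (up, gap in b), 2 = Y (left, gap in a)
struct DP {
  int m, n;
  std::vector<double> M, X, Y;
  std::vector<signed char> pM, pX, pY; // predecessor state, -1 = local start
  DP(int m_, int n_) : m(m_), n(n_),
    M((m_ + 1) * (n_ + 1), NEG_INF), X(M), Y(M),
    pM((m_ + 1) * (n_ + 1), -1), pX(pM), pY(pM) {}
  inline int at(int i, int j) const { return i * (n + 1) + j; }
};

// preference M > X > Y on exact ties
static inline void best3(double m, double x, double y, double &val, signed char &arg) {
  val = m; arg = 0;
  if (x > val) { val = x; arg = 1; }
  if (y > val) { val = y; arg = 2; }
}

static void fill(DP &dp, const IntegerVector &a, const IntegerVector &b,
                 const NumericMatrix &S, double go, double ge, bool local) {
  int m = dp.m, n = dp.n;
  if (!local) {
    dp.M[dp.at(0, 0)] = 0.0;
    for (int i = 1; i <= m; ++i) {
      dp.X[dp.at(i, 0)] = -(go + i * ge);
      dp.pX[dp.at(i, 0)] = (i == 1) ? 0 : 1;
    }
    for (int j = 1; j <= n; ++j) {
      dp.Y[dp.at(0, j)] = -(go + j * ge);
      dp.pY[dp.at(0, j)] = (j == 1) ? 0 : 2;
    }
  }
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      int ij = dp.at(i, j), up = dp.at(i - 1, j), lf = dp.at(i, j - 1),
          di = dp.at(i - 1, j - 1);
      double s = S(a[i - 1], b[j - 1]);
      double val; signed char arg;
      best3(dp.M[di], dp.X[di], dp.Y[di], val, arg);
      if (local && (val < 0.0 || val == NEG_INF)) { val = 0.0; arg = -1; }
      dp.M[ij] = (val == NEG_INF) ? NEG_INF : s + val;
      dp.pM[ij] = arg;
      best3(dp.M[up] - (go + ge), dp.X[up] - ge, dp.Y[up] - (go + ge), val, arg);
      dp.X[ij] = val; dp.pX[ij] = arg;
      best3(dp.M[lf] - (go + ge), dp.X[lf] - (go + ge), dp.Y[lf] - ge, val, arg);
      dp.Y[ij] = val; dp.pY[ij] = arg;
    }
  }
}

// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(std::string sa, std::string sb,
                    IntegerVector a, IntegerVector b,
                    NumericMatrix S, double gap_open, double gap_extend,
                    bool local) {
  int m = a.size(), n = b.size();
  DP dp(m, n);
  fill(dp, a, b, S, gap_open, gap_extend, local);
  int bi = m, bj = n; signed char bst = 0; double score;
  if (!local) {
    signed char arg; double val;
    best3(dp.M[dp.at(m, n)], dp.X[dp.at(m, n)], dp.Y[dp.at(m, n)], val, arg);
    score = val; bst = arg;
  } else {
    score = 0.0; bi = 0; bj = 0; bst = 0;
    for (int i = 1; i <= m; ++i)
      for (int j = 1; j <= n; ++j)
        if (dp.M[dp.at(i, j)] > score) { score = dp.M[dp.at(i, j)]; bi = i; bj = j; }
    if (score <= 0.0)
      return List::create(_["score"] = 0.0, _["a"] = "", _["b"] = "",
                          _["start_a"] = NA_INTEGER, _["end_a"] = NA_INTEGER,
                          _["start_b"] = NA_INTEGER, _["end_b"] = NA_INTEGER);
  }
  // traceback
  std::string aa, bb;
  int i = bi, j = bj; signed char st = bst;
  while (true) {
    if (!local && i == 0 && j == 0) break;
    if (local && st == 0 && dp.pM[dp.at(i, j)] == -1) {
      aa.push_back(sa[i - 1]); bb.push_back(sb[j - 1]);
      --i; --j;
      break;
    }
    signed char prev;
    if (st == 0) {
      prev = dp.pM[dp.at(i, j)];
      aa.push_back(sa[i - 1]); bb.push_back(sb[j - 1]);
      --i; --j;
    } else if (st == 1) {
      prev = dp.pX[dp.at(i, j)];
      aa.push_back(sa[i - 1]); bb.push_back('-');
      --i;
    } else {
      prev = dp.pY[dp.at(i, j)];
      aa.push_back('-'); bb.push_back(sb[j - 1]);
      --j;
    }
    st = prev;
    if (!local && i == 0 && j == 0) break;
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["score"] = score, _["a"] = aa, _["b"] = bb,
                      _["start_a"] = local ? i + 1 : 1,
                      _["end_a"] = local ? bi : m,
                      _["start_b"] = local ? j + 1 : 1,
                      _["end_b"] = local ? bj : n);
}
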
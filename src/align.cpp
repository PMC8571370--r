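#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global alignment with affine gap costs (Gotoh). A gap of length k costs
// open + k * extend. Traceback tie-break: diagonal > up (gap in b) > left
// (gap in a), applied both to state selection and to within-state moves,
// so the alignment is deterministic. Scores use two rolling rows; the
// traceback keeps one byte per cell and state.

static const double NEG_INF = -1e18;

static inline double subScore(char x, char y, double match, double mismatch) {
  // N never matches anything (conservative).
  if (x == 'N' || y == 'N') return mismatch;
  return (x == y) ? match : mismatch;
}

// shared DP core: scoreAt(i, j) gives the substitution score of pairing
// position i of a (0-based) with position j of b
template <typename ScoreFn>
static void gotohFill(int n, int m, double gapOpen, double gapExtend,
                      ScoreFn scoreAt,
                      std::vector<signed char>& tM,
                      std::vector<signed char>& tX,
                      std::vector<signed char>& tY,
                      double& bestScore, int& bestState) {
  const int W = m + 1;
  std::vector<double> M0(W), X0(W), Y0(W), M1(W), X1(W), Y1(W);
  M0[0] = 0.0; X0[0] = NEG_INF; Y0[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    M0[j] = NEG_INF; X0[j] = NEG_INF;
    Y0[j] = -(gapOpen + j * gapExtend);
    tY[j] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    M1[0] = NEG_INF; Y1[0] = NEG_INF;
    X1[0] = -(gapOpen + i * gapExtend);
    tX[i * W] = 1;
    for (int j = 1; j <= m; ++j) {
      // M from (i-1, j-1); preference M > X > Y
      double best = M0[j - 1]; signed char st = 0;
      if (X0[j - 1] > best) { best = X0[j - 1]; st = 1; }
      if (Y0[j - 1] > best) { best = Y0[j - 1]; st = 2; }
      M1[j] = (best > NEG_INF / 2) ? best + scoreAt(i - 1, j - 1) : NEG_INF;
      tM[i * W + j] = st;
      // X from (i-1, j): open from M/Y, extend from X
      double vM = M0[j] - gapOpen - gapExtend;
      double vX = X0[j] - gapExtend;
      double vY = Y0[j] - gapOpen - gapExtend;
      best = vM; st = 0;
      if (vX > best) { best = vX; st = 1; }
      if (vY > best) { best = vY; st = 2; }
      X1[j] = (best > NEG_INF / 2) ? best : NEG_INF;
      tX[i * W + j] = st;
      // Y from (i, j-1)
      vM = M1[j - 1] - gapOpen - gapExtend;
      vX = X1[j - 1] - gapOpen - gapExtend;
      vY = Y1[j - 1] - gapExtend;
      best = vM; st = 0;
      if (vX > best) { best = vX; st = 1; }
      if (vY > best) { best = vY; st = 2; }
      Y1[j] = (best > NEG_INF / 2) ? best : NEG_INF;
      tY[i * W + j] = st;
    }
    std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
  }
  bestScore = M0[m]; bestState = 0;
  if (X0[m] > bestScore) { bestScore = X0[m]; bestState = 1; }
  if (Y0[m] > bestScore) { bestScore = Y0[m]; bestState = 2; }
  if (n == 0 && m == 0) { bestScore = 0.0; bestState = 0; }
}

// [[Rcpp::export(name = ".nwAffine")]]
List nwAffine(std::string a, std::string b,
              double match, double mismatch,
              double gapOpen, double gapExtend) {
  const int n = a.size(), m = b.size();
  const int W = m + 1;
  std::vector<signed char> tM((n + 1) * W, 0), tX((n + 1) * W, 0),
      tY((n + 1) * W, 0);
  double score; int state;
  gotohFill(n, m, gapOpen, gapExtend,
            [&](int i, int j) { return subScore(a[i], b[j], match, mismatch); },
            tM, tX, tY, score, state);
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (j == 0) state = 1;
    else if (i == 0) state = 2;
    if (state == 0) {
      signed char prev = tM[i * W + j];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      signed char prev = tX[i * W + j];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = prev;
    } else {
      signed char prev = tY[i * W + j];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["score"] = score, _["a"] = ra, _["b"] = rb);
}

// Profile-profile global alignment with affine gaps. Profiles are 5 x L
// frequency matrices (rows A, C, G, T, gap; columns sum to 1). The score of
// pairing two columns is the expected substitution score over residue pairs;
// pre-existing gap mass scores 0 against everything. Returns, per merged
// column, the 1-based source column in each profile (0 = new gap).

// [[Rcpp::export(name = ".profileAlign")]]
List profileAlign(NumericMatrix A, NumericMatrix B,
                  double match, double mismatch,
                  double gapOpen, double gapExtend) {
  const int n = A.ncol(), m = B.ncol();
  const int W = m + 1;
  std::vector<signed char> tM((n + 1) * W, 0), tX((n + 1) * W, 0),
      tY((n + 1) * W, 0);
  const double* pa = A.begin();
  const double* pb = B.begin();
  auto colScore = [&](int i, int j) {
    const double* fa = pa + 5 * i;
    const double* fb = pb + 5 * j;
    double s = 0.0;
    for (int x = 0; x < 4; ++x) {
      if (fa[x] == 0.0) continue;
      for (int y = 0; y < 4; ++y)
        s += fa[x] * fb[y] * ((x == y) ? match : mismatch);
    }
    return s;
  };
  double score; int state;
  gotohFill(n, m, gapOpen, gapExtend, colScore, tM, tX, tY, score, state);
  std::vector<int> va, vb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (j == 0) state = 1;
    else if (i == 0) state = 2;
    if (state == 0) {
      signed char prev = tM[i * W + j];
      va.push_back(i); vb.push_back(j); --i; --j; state = prev;
    } else if (state == 1) {
      signed char prev = tX[i * W + j];
      va.push_back(i); vb.push_back(0); --i; state = prev;
    } else {
      signed char prev = tY[i * W + j];
      va.push_back(0); vb.push_back(j); --j; state = prev;
    }
  }
  std::reverse(va.begin(), va.end());
  std::reverse(vb.begin(), vb.end());
  return List::create(_["score"] = score,
                      _["a"] = IntegerVector(va.begin(), va.end()),
                      _["b"] = IntegerVector(vb.begin(), vb.end()));
}
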
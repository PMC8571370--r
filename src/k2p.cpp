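#include <Rcpp.h>
using namespace Rcpp;

// Pairwise-deletion site counts for all row pairs of an integer-coded
// alignment (A=1, C=2, G=3, T=4, gap=0, ambiguous=5). Returns, per pair,
// the compared-site count L, transitions nP and transversions nQ --
// the inputs of the K2P formula. Columns where either row is ambiguous
// or gap are excluded per pair (pairwise deletion).

// [[Rcpp::export(name = ".pairCountsAll")]]
List pairCountsAll(IntegerMatrix codes) {
  const int n = codes.nrow(), m = codes.ncol();
  IntegerMatrix L(n, n), P(n, n), Q(n, n);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int l = 0, p = 0, q = 0;
      for (int c = 0; c < m; ++c) {
        const int a = codes(i, c), b = codes(j, c);
        if (a < 1 || a > 4 || b < 1 || b > 4) continue;
        ++l;
        if (a != b) {
          const bool purA = (a == 1 || a == 3), purB = (b == 1 || b == 3);
          if (purA == purB) ++p; else ++q;
        }
      }
      L(i, j) = L(j, i) = l;
      P(i, j) = P(j, i) = p;
      Q(i, j) = Q(j, i) = q;
    }
  }
  return List::create(_["L"] = L, _["nP"] = P, _["nQ"] = Q);
}
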
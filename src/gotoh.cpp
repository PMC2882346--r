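#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch/Gotoh) alignment over a precomputed
// position-by-position score matrix. A gap run of length L costs
// gap_open + (L - 1) * gap_extend. Works for single sequences and for
// profile columns alike: the caller supplies S[i, j] = score of aligning
// position i of the first object with position j of the second.
//
// Traceback tie-breaking (fixed contract): substitution is preferred over
// a gap in the second object (consume first), which is preferred over a
// gap in the first object; the same ordering is used when choosing the
// predecessor state inside the gap matrices.
//
// Returns integer index vectors for both objects, 0 marking a gap column.

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(NumericMatrix S, double gap_open, double gap_extend) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e300;

  if (n == 0 || m == 0) {
    int len = n + m;
    IntegerVector ia(len), ib(len);
    double sc = 0.0;
    for (int k = 0; k < n; ++k) { ia[k] = k + 1; ib[k] = 0; }
    for (int k = 0; k < m; ++k) { ia[n + k] = 0; ib[n + k] = k + 1; }
    if (len > 0) sc = -(gap_open + (len - 1) * gap_extend);
    return List::create(_["i1"] = ia, _["i2"] = ib, _["score"] = sc);
  }

  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // state of the predecessor, encoded 0 = M, 1 = X (gap in second), 2 = Y
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(gap_open + (i - 1) * gap_extend);
    tbX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -(gap_open + (j - 1) * gap_extend);
    tbY(0, j) = 2;
  }
  tbX(1, 0) = 0; tbY(0, 1) = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // substitution
      double best = M(i - 1, j - 1); int st = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); st = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); st = 2; }
      M(i, j) = best + S(i - 1, j - 1); tbM(i, j) = st;

      // gap in second object (consume i)
      best = M(i - 1, j) - gap_open; st = 0;
      if (X(i - 1, j) - gap_extend > best) { best = X(i - 1, j) - gap_extend; st = 1; }
      if (Y(i - 1, j) - gap_open > best) { best = Y(i - 1, j) - gap_open; st = 2; }
      X(i, j) = best; tbX(i, j) = st;

      // gap in first object (consume j)
      best = M(i, j - 1) - gap_open; st = 0;
      if (X(i, j - 1) - gap_open > best) { best = X(i, j - 1) - gap_open; st = 1; }
      if (Y(i, j - 1) - gap_extend > best) { best = Y(i, j - 1) - gap_extend; st = 2; }
      Y(i, j) = best; tbY(i, j) = st;
    }
  }

  double score = M(n, m); int state = 0;
  if (X(n, m) > score) { score = X(n, m); state = 1; }
  if (Y(n, m) > score) { score = Y(n, m); state = 2; }

  std::vector<int> ia, ib;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tbM(i, j);
      ia.push_back(i); ib.push_back(j); --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tbX(i, j);
      ia.push_back(i); ib.push_back(0); --i; state = prev;
    } else {
      int prev = tbY(i, j);
      ia.push_back(0); ib.push_back(j); --j; state = prev;
    }
  }
  std::reverse(ia.begin(), ia.end());
  std::reverse(ib.begin(), ib.end());

  return List::create(_["i1"] = wrap(ia), _["i2"] = wrap(ib),
                      _["score"] = score);
}
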
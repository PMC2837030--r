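#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with position-dependent two-sided gap
// costs. Diagonal move into (i,j) adds S(i,j); vertical move (gap in the
// second profile, consuming position i of the first) subtracts G(i,j);
// horizontal move subtracts C(i,j). Cells are floored at 0. Ties are broken
// deterministically: diagonal > vertical > horizontal > stop. Traceback
// starts at the first (row-major) occurrence of the global maximum.
// [[Rcpp::export(name = ".sw_positional_cpp")]]
List sw_positional_cpp(NumericMatrix S, NumericMatrix G, NumericMatrix C) {
  const int m = S.nrow(), n = S.ncol();
  if (m < 1 || n < 1) stop("empty score matrix");
  NumericMatrix M(m + 1, n + 1);
  IntegerMatrix tb(m + 1, n + 1); // 0 stop, 1 diag, 2 vertical, 3 horizontal
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double d = M(i - 1, j - 1) + S(i - 1, j - 1);
      double u = M(i - 1, j) - G(i - 1, j - 1);
      double l = M(i, j - 1) - C(i - 1, j - 1);
      double v = d; int mv = 1;
      if (u > v) { v = u; mv = 2; }
      if (l > v) { v = l; mv = 3; }
      if (v <= 0.0) { v = 0.0; mv = 0; }
      M(i, j) = v; tb(i, j) = mv;
      if (v > best) { best = v; bi = i; bj = j; }
    }
  }
  std::vector<int> pi, pj, pmove;
  int i = bi, j = bj;
  while (i > 0 && j > 0 && tb(i, j) != 0) {
    int mv = tb(i, j);
    pmove.push_back(mv);
    if (mv == 1) { pi.push_back(i); pj.push_back(j); --i; --j; }
    else if (mv == 2) { pi.push_back(i); pj.push_back(NA_INTEGER); --i; }
    else { pi.push_back(NA_INTEGER); pj.push_back(j); --j; }
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  std::reverse(pmove.begin(), pmove.end());
  return List::create(_["score"] = best,
                      _["end_i"] = bi, _["end_j"] = bj,
                      _["start_i"] = i, _["start_j"] = j,
                      _["path_i"] = wrap(pi), _["path_j"] = wrap(pj),
                      _["moves"] = wrap(pmove));
}
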
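#include <Rcpp.h>
using namespace Rcpp;

// Dynamic-time-warping dynamic program with the classic step set
// {(1,1),(1,0),(0,1)}, absolute-difference local cost, endpoints anchored,
// no window constraint. The accumulated cost includes the local cost of
// every cell on the path (the start cell too). Traceback ties prefer the
// diagonal, then the query step (i-1), then the reference step (j-1), so
// the returned path is deterministic.
// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericVector x, NumericVector y) {
  const int n = x.size(), m = y.size();
  if (n < 1 || m < 1) stop("empty sequence");
  NumericMatrix D(n, m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) {
      double c = std::abs(x[i] - y[j]);
      if (i == 0 && j == 0) {
        D(i, j) = c;
      } else {
        double best = R_PosInf;
        if (i > 0 && j > 0) best = D(i - 1, j - 1);
        if (i > 0 && D(i - 1, j) < best) best = D(i - 1, j);
        if (j > 0 && D(i, j - 1) < best) best = D(i, j - 1);
        D(i, j) = c + best;
      }
    }
  }
  // traceback
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  pi.push_back(i + 1); pj.push_back(j + 1);
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      double d = D(i - 1, j - 1), u = D(i - 1, j), l = D(i, j - 1);
      if (d <= u && d <= l) { --i; --j; }
      else if (u <= l) { --i; }
      else { --j; }
    } else if (i > 0) { --i; }
    else { --j; }
    pi.push_back(i + 1); pj.push_back(j + 1);
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["cost"] = D(n - 1, m - 1),
                      _["i"] = wrap(pi), _["j"] = wrap(pj));
}
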
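#include <Rcpp.h>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Global pairwise alignment with free end gaps, for short RNA sequences
// (matures ~22 nt, hairpins ~60-110 nt). Fixed scoring: match +1,
// mismatch -1, gap -2; terminal gaps cost nothing.
//
// Deterministic tie-breaks:
//   * cell fill: diagonal > up (gap in b) > left (gap in a);
//   * terminal cell: the bottom-right corner, then the last column scanned
//     top-to-bottom, then the last row scanned left-to-right, replaced only
//     on a strictly better score.
// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  NumericMatrix H(n + 1, m + 1);
  IntegerMatrix P(n + 1, m + 1); // 1 diag, 2 up, 3 left
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = (a[i - 1] == b[j - 1]) ? 1.0 : -1.0;
      double best = H(i - 1, j - 1) + s;
      int p = 1;
      const double up = H(i - 1, j) - 2.0;
      if (up > best) { best = up; p = 2; }
      const double left = H(i, j - 1) - 2.0;
      if (left > best) { best = left; p = 3; }
      H(i, j) = best;
      P(i, j) = p;
    }
  }
  int bi = n, bj = m;
  double best = H(n, m);
  for (int i = 0; i <= n; ++i)
    if (H(i, m) > best) { best = H(i, m); bi = i; bj = m; }
  for (int j = 0; j <= m; ++j)
    if (H(n, j) > best) { best = H(n, j); bi = n; bj = j; }

  std::string ra, rb; // built right-to-left, reversed at the end
  if (bj == m) {
    for (int i = n; i > bi; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  } else {
    for (int j = m; j > bj; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }
  }
  int i = bi, j = bj;
  while (i > 0 && j > 0) {
    const int p = P(i, j);
    if (p == 1) {
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]); --i; --j;
    } else if (p == 2) {
      ra.push_back(a[i - 1]); rb.push_back('-'); --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]); --j;
    }
  }
  while (i > 0) { ra.push_back(a[i - 1]); rb.push_back('-'); --i; }
  while (j > 0) { ra.push_back('-'); rb.push_back(b[j - 1]); --j; }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = best);
}
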
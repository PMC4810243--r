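#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Unit-cost global alignment (Levenshtein) with full traceback.
// Tie-break order at equal cost: substitution/match, then gap in `a`
// (column consumes a base of b only), then gap in `b`.  This makes the
// aligned column layout, and hence region-restricted difference counts,
// deterministic.
//
// [[Rcpp::export(name = ".align_edit_cpp")]]
List align_edit_cpp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  // D has (n+1) x (m+1) entries; store as vector.
  std::vector<int> D((n + 1) * (m + 1));
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  for (int i = 0; i <= n; ++i) D[at(i, 0)] = i;
  for (int j = 0; j <= m; ++j) D[at(0, j)] = j;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int sub = D[at(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? 0 : 1);
      int gap_a = D[at(i, j - 1)] + 1;  // gap in a, consume b[j-1]
      int gap_b = D[at(i - 1, j)] + 1;  // gap in b, consume a[i-1]
      int best = sub;
      if (gap_a < best) best = gap_a;
      if (gap_b < best) best = gap_b;
      D[at(i, j)] = best;
    }
  }
  // Traceback from (n, m) honouring the tie-break preference.
  std::string ra, rb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int cur = D[at(i, j)];
    if (i > 0 && j > 0 &&
        cur == D[at(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? 0 : 1)) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      --i; --j;
    } else if (j > 0 && cur == D[at(i, j - 1)] + 1) {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      --j;
    } else {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      --i;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  const int L = ra.size();
  // Per-column difference indicator and source coordinates (0 = gap).
  IntegerVector diff(L), pos_a(L), pos_b(L);
  int ia = 0, ib = 0;
  for (int c = 0; c < L; ++c) {
    bool ga = ra[c] == '-', gb = rb[c] == '-';
    pos_a[c] = ga ? 0 : ++ia;
    pos_b[c] = gb ? 0 : ++ib;
    diff[c] = (ga || gb || ra[c] != rb[c]) ? 1 : 0;
  }
  return List::create(
      _["delta"] = D[at(n, m)], _["aligned_length"] = L,
      _["aligned_a"] = ra, _["aligned_b"] = rb, _["diff"] = diff,
      _["pos_a"] = pos_a, _["pos_b"] = pos_b);
}
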
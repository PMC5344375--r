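#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Threshold-bounded Levenshtein distance restricted to the +/- tau diagonal
// band, with row-min early termination. Inputs are code-point vectors.
// Returns c(distance, cells_touched); distance is -1 when it exceeds tau.
// Unit costs for insert/delete/substitute.
// [[Rcpp::export(name = ".ed_banded_int")]]
IntegerVector ed_banded_int(IntegerVector a, IntegerVector b, int tau) {
  if (tau < 0) stop("tau must be >= 0");
  // keep `a` the shorter string so the band runs over min(|a|,|b|) rows
  if (a.size() > b.size()) std::swap(a, b);
  const int n = a.size(), m = b.size();
  long cells = 0;
  if (m - n > tau) return IntegerVector::create(-1, 0);
  const int INF = INT_MAX / 4;
  // prev[k], cur[k] hold D[i][j] for j = i - tau + k, k in 0..2*tau
  const int w = 2 * tau + 1;
  std::vector<int> prev(w, INF), cur(w, INF);
  // row 0: D[0][j] = j for j in [0, tau]
  for (int k = 0; k < w; ++k) {
    int j = k - tau;
    if (j >= 0 && j <= m) { prev[k] = j; ++cells; }
  }
  for (int i = 1; i <= n; ++i) {
    int rowmin = INF;
    for (int k = 0; k < w; ++k) cur[k] = INF;
    int jlo = i - tau < 0 ? 0 : i - tau;
    int jhi = i + tau > m ? m : i + tau;
    for (int j = jlo; j <= jhi; ++j) {
      int k = j - i + tau;
      int best = INF;
      if (j > 0) {
        // substitution / match: D[i-1][j-1] at offset k in prev
        if (prev[k] < INF) {
          int c = prev[k] + (a[i - 1] == b[j - 1] ? 0 : 1);
          if (c < best) best = c;
        }
        // insertion into a (left neighbour in same row): offset k-1 in cur
        if (k > 0 && cur[k - 1] < INF && cur[k - 1] + 1 < best)
          best = cur[k - 1] + 1;
      } else {
        best = i;  // D[i][0] = i, only reachable while i <= tau
      }
      // deletion from a (cell above): offset k+1 in prev
      if (k + 1 < w && prev[k + 1] < INF && prev[k + 1] + 1 < best)
        best = prev[k + 1] + 1;
      cur[k] = best;
      ++cells;
      if (best < rowmin) rowmin = best;
    }
    if (rowmin > tau) return IntegerVector::create(-1, (int)cells);
    std::swap(prev, cur);
  }
  int d = prev[m - n + tau];
  if (d > tau) return IntegerVector::create(-1, (int)cells);
  return IntegerVector::create(d, (int)cells);
}
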
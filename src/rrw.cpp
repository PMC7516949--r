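#include <Rcpp.h>
using namespace Rcpp;

// Return Random Walk edge scores for a weighted digraph.
//
// For each ordered pair (i, j), i != j, scores the best two-step go-and-return
// cycle: go i -> k -> j, return j -> l -> i with l != k,
//   We_ij = max_k max_{l != k} p_k(j|i) * p_l(i|j),
// where p_k(j|i) = W(i,k) W(k,j) / (d_i d_j). The degree vector d is supplied
// by the caller so the convention lives in one place (R side).
//
// Tie-breaking: the lexicographically smallest (k, l) attaining the maximum,
// matching a k-outer / l-inner scan with strictly-greater-wins. Products are
// formed with the same expression order as the R brute-force oracle so that
// equality comparisons are exact in IEEE arithmetic.
//
// A pair with best product <= 0 (no usable cycle) gets We_ij = 0 and NA
// transit indices.

// [[Rcpp::export]]
List rrw_core(NumericMatrix W, NumericVector d) {
  const int n = W.nrow();
  NumericMatrix We(n, n);
  IntegerMatrix kstar(n, n), lstar(n, n);
  std::fill(kstar.begin(), kstar.end(), NA_INTEGER);
  std::fill(lstar.begin(), lstar.end(), NA_INTEGER);

  std::vector<double> out(n), ret(n);

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      const double dij = d[i] * d[j];
      if (dij <= 0.0) continue; // no incident weight on an endpoint
      // candidate go and return probabilities per transit node
      // (zero diagonal of W makes k == i, k == j vanish automatically)
      for (int k = 0; k < n; ++k) {
        out[k] = W(i, k) * W(k, j) / dij;
        ret[k] = W(j, k) * W(k, i) / dij;
      }
      // top-2 of ret with smallest indices
      int r1 = -1, r2 = -1;
      for (int l = 0; l < n; ++l) {
        if (ret[l] <= 0.0) continue;
        if (r1 < 0 || ret[l] > ret[r1]) { r2 = r1; r1 = l; }
        else if (r2 < 0 || ret[l] > ret[r2]) { r2 = l; }
      }
      if (r1 < 0) continue; // no return path at all
      double best = 0.0;
      int bk = -1;
      for (int k = 0; k < n; ++k) {
        if (out[k] <= 0.0) continue;
        int l = (k == r1) ? r2 : r1;
        if (l < 0) continue; // only return transit coincides with k
        double cand = out[k] * ret[l];
        if (cand > best) { best = cand; bk = k; }
      }
      if (bk < 0 || best <= 0.0) continue;
      // recover the smallest l != bk attaining the maximum for this k
      int bl = -1;
      for (int l = 0; l < n; ++l) {
        if (l == bk || ret[l] <= 0.0) continue;
        if (out[bk] * ret[l] == best) { bl = l; break; }
      }
      We(i, j) = best;
      kstar(i, j) = bk + 1; // 1-based for R
      lstar(i, j) = bl + 1;
    }
  }
  return List::create(_["We"] = We, _["kstar"] = kstar, _["lstar"] = lstar);
}
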
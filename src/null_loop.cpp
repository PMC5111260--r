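#include <Rcpp.h>
using namespace Rcpp;

// Permutation null for network connectedness with expression-rank matching.
//
// Genes are indexed by their within-stratum expression rank position
// (0-based, 0 = highest mean expression).  For each query gene, one matched
// gene is drawn uniformly from the non-query, not-yet-used genes whose rank
// lies within `window` positions of the query gene's rank; if that window is
// exhausted it is widened symmetrically to the nearest eligible gene.  The
// edge count of the tau-thresholded network on the sampled set is recorded.
//
// adj_row[p] maps a rank position to its row in `adj` (-1 if the gene's
// correlations were not materialised; such positions are never eligible).
// Uses R's RNG so results are governed by set.seed().
// [[Rcpp::export]]
IntegerVector cpp_null_connectedness(const LogicalMatrix& adj,
                                     const IntegerVector& adj_row,
                                     const IntegerVector& deg_pos,
                                     const LogicalVector& is_deg,
                                     int window, int B) {
  const int n = adj_row.size();
  const int k = deg_pos.size();
  IntegerVector out(B);
  std::vector<char> used(n);
  std::vector<int> cand;
  std::vector<int> sampled(k);

  for (int b = 0; b < B; ++b) {
    std::fill(used.begin(), used.end(), 0);
    for (int i = 0; i < k; ++i) {
      int p = deg_pos[i];
      int w = window;
      cand.clear();
      while (cand.empty()) {
        int lo = p - w < 0 ? 0 : p - w;
        int hi = p + w >= n ? n - 1 : p + w;
        for (int j = lo; j <= hi; ++j) {
          if (!is_deg[j] && !used[j] && adj_row[j] >= 0) cand.push_back(j);
        }
        if (cand.empty()) {
          if (w >= n) stop("no eligible matched gene for a query gene");
          ++w;  // widen to the nearest eligible gene
        }
      }
      int pick = cand[(int)(unif_rand() * cand.size()) % cand.size()];
      used[pick] = 1;
      sampled[i] = adj_row[pick];
    }
    int edges = 0;
    for (int i = 0; i < k; ++i) {
      for (int j = i + 1; j < k; ++j) {
        if (adj(sampled[i], sampled[j])) ++edges;
      }
    }
    out[b] = edges;
  }
  return out;
}
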
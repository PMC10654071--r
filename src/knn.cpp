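#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// k smallest entries per row of a squared-distance matrix, ordered by
// increasing value with ties broken by column index. Returns 1-based column
// indices, one row per query.
// [[Rcpp::export]]
IntegerMatrix knn_select(NumericMatrix d2, int k) {
  const int nq = d2.nrow(), nd = d2.ncol();
  if (k > nd) k = nd;
  IntegerMatrix out(nq, k);
  std::vector<int> idx(nd);
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nd; ++j) idx[j] = j;
    const double* row0 = &d2(i, 0);
    // d2 is column-major; gather the row first for cache-friendly compares
    std::vector<double> r(nd);
    for (int j = 0; j < nd; ++j) r[j] = row0[(R_xlen_t)j * nq];
    std::partial_sort(idx.begin(), idx.begin() + k, idx.end(),
                      [&r](int a, int b) {
                        if (r[a] != r[b]) return r[a] < r[b];
                        return a < b;
                      });
    for (int j = 0; j < k; ++j) out(i, j) = idx[j] + 1;
  }
  return out;
}
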
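#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// k smallest entries per row of a distance matrix (ascending), ties broken
// by lowest column index; non-finite entries are excluded; if fewer than k
// candidates remain, the nearest available ones are recycled.
// [[Rcpp::export(name = ".topk_rows_cpp")]]
IntegerMatrix topk_rows_cpp(NumericMatrix d, int k) {
  const int m = d.nrow(), n = d.ncol();
  IntegerMatrix out(m, k);
  std::vector<int> idx(n);
  for (int i = 0; i < m; ++i) {
    idx.clear();
    for (int j = 0; j < n; ++j) {
      if (R_finite(d(i, j))) idx.push_back(j);
    }
    const int navail = (int)idx.size();
    if (navail == 0) stop("row %d has no finite distances", i + 1);
    const int kk = std::min(k, navail);
    NumericMatrix::Row row = d(i, _);
    std::partial_sort(idx.begin(), idx.begin() + kk, idx.end(),
                      [&row](int a, int b) {
                        if (row[a] != row[b]) return row[a] < row[b];
                        return a < b;
                      });
    for (int j = 0; j < k; ++j) out(i, j) = idx[j % kk] + 1;
  }
  return out;
}

// greedy farthest point sampling (max-min, ties -> lowest index)
// [[Rcpp::export(name = ".fps_cpp")]]
IntegerVector fps_cpp(NumericMatrix coords, int m, int start) {
  const int n = coords.nrow(), d = coords.ncol();
  IntegerVector sel(m);
  std::vector<double> mind(n);
  sel[0] = start;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int c = 0; c < d; ++c) {
      const double df = coords(i, c) - coords(start - 1, c);
      s += df * df;
    }
    mind[i] = s;
  }
  for (int t = 1; t < m; ++t) {
    int best = 0;
    for (int i = 1; i < n; ++i) {
      if (mind[i] > mind[best]) best = i;
    }
    sel[t] = best + 1;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double df = coords(i, c) - coords(best, c);
        s += df * df;
      }
      if (s < mind[i]) mind[i] = s;
    }
  }
  return sel;
}
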
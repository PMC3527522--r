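#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// 2-D running median with a k x k window, edge-truncated; NA cells (grid
// positions without a probe) are ignored in each window and stay NA in the
// output. Brute-force nth_element per window: grids here are a few hundred
// cells a side, so this is plenty fast.
// [[Rcpp::export(name = ".median_filter_2d")]]
NumericMatrix median_filter_2d(NumericMatrix x, int k) {
  if (k < 1 || k % 2 == 0) stop("window size k must be a positive odd integer");
  int nr = x.nrow(), nc = x.ncol(), h = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)k * k);
  for (int i = 0; i < nr; ++i) {
    int r0 = std::max(0, i - h), r1 = std::min(nr - 1, i + h);
    for (int j = 0; j < nc; ++j) {
      if (NumericMatrix::is_na(x(i, j))) { out(i, j) = NA_REAL; continue; }
      int c0 = std::max(0, j - h), c1 = std::min(nc - 1, j + h);
      buf.clear();
      for (int r = r0; r <= r1; ++r)
        for (int c = c0; c <= c1; ++c)
          if (!NumericMatrix::is_na(x(r, c))) buf.push_back(x(r, c));
      size_t n = buf.size();
      if (n == 0) { out(i, j) = NA_REAL; continue; }
      size_t mid = n / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double m = buf[mid];
      if (n % 2 == 0) {
        double lo = *std::max_element(buf.begin(), buf.begin() + mid);
        m = 0.5 * (m + lo);
      }
      out(i, j) = m;
    }
  }
  return out;
}
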
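#include <Rcpp.h>
using namespace Rcpp;

// 2-D convolution with an odd-sized kernel and replicate (edge-clamp)
// padding. Kernel is applied as a correlation over the (row, col) window,
// matching the shift-add reference implementation in R.
// [[Rcpp::export]]
NumericMatrix conv2_replicate_cpp(const NumericMatrix& x,
                                  const NumericMatrix& k) {
  const int n = x.nrow(), m = x.ncol();
  const int kn = k.nrow(), km = k.ncol();
  const int rn = (kn - 1) / 2, rm = (km - 1) / 2;
  NumericMatrix out(n, m);
  const double* xp = x.begin();
  double* op = out.begin();
  std::vector<double> kv(k.begin(), k.end());
  // interior: no clamping needed
  for (int j = rm; j < m - rm; ++j) {
    for (int i = rn; i < n - rn; ++i) {
      double acc = 0.0;
      int t = 0;
      for (int dj = -rm; dj <= rm; ++dj) {
        const double* col = xp + (size_t)(j + dj) * n + i;
        for (int di = -rn; di <= rn; ++di, ++t) {
          acc += kv[t] * col[di];
        }
      }
      op[(size_t)j * n + i] = acc;
    }
  }
  // borders: replicate padding
  for (int j = 0; j < m; ++j) {
    const bool jedge = (j < rm) || (j >= m - rm);
    for (int i = 0; i < n; ++i) {
      if (!jedge && i >= rn && i < n - rn) { i = n - rn - 1; continue; }
      double acc = 0.0;
      int t = 0;
      for (int dj = -rm; dj <= rm; ++dj) {
        int cj = j + dj;
        if (cj < 0) cj = 0; else if (cj >= m) cj = m - 1;
        const double* col = xp + (size_t)cj * n;
        for (int di = -rn; di <= rn; ++di, ++t) {
          int ci = i + di;
          if (ci < 0) ci = 0; else if (ci >= n) ci = n - 1;
          acc += kv[t] * col[ci];
        }
      }
      op[(size_t)j * n + i] = acc;
    }
  }
  return out;
}

// Summed-area table with a zero top row and left column.
// [[Rcpp::export]]
NumericMatrix integral_image_cpp(const NumericMatrix& x) {
  const int n = x.nrow(), m = x.ncol();
  NumericMatrix ii(n + 1, m + 1);
  for (int j = 1; j <= m; ++j) {
    double rowsum = 0.0;
    for (int i = 1; i <= n; ++i) {
      rowsum += x(i - 1, j - 1);
      ii(i, j) = ii(i, j - 1) + rowsum;
    }
  }
  return ii;
}
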
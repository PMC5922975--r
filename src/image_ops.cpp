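// Hot inner loops for the dense-trajectory feature stage: summed-area
// tables, box filtering and median flow filtering. Kept minimal; all
// orchestration stays in R.

#include <Rcpp.h>
#include <algorithm>

using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix integral_c(const NumericMatrix& img) {
  const int n = img.nrow(), m = img.ncol();
  NumericMatrix ii(n + 1, m + 1);
  for (int j = 0; j < m; ++j) {
    double rowsum = 0.0;
    const double* col = &img(0, j);
    double* out = &ii(0, j + 1);
    const double* prev = &ii(0, j);
    for (int i = 0; i < n; ++i) {
      rowsum += col[i];
      out[i + 1] = prev[i + 1] + rowsum;
    }
  }
  return ii;
}

// [[Rcpp::export]]
NumericMatrix box_filter_c(const NumericMatrix& img, const int r) {
  const int n = img.nrow(), m = img.ncol();
  NumericMatrix ii = integral_c(img);
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    const int ylo = std::max(j - r, 0), yhi = std::min(j + r, m - 1) + 1;
    const double* chi = &ii(0, yhi);
    const double* clo = &ii(0, ylo);
    for (int i = 0; i < n; ++i) {
      const int xlo = std::max(i - r, 0), xhi = std::min(i + r, n - 1) + 1;
      out(i, j) = chi[xhi] - clo[xhi] - chi[xlo] + clo[xlo];
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix median3_c(const NumericMatrix& img) {
  const int n = img.nrow(), m = img.ncol();
  NumericMatrix out(n, m);
  double v[9];
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      int k = 0;
      for (int dj = -1; dj <= 1; ++dj) {
        int jj = std::min(std::max(j + dj, 0), m - 1);
        for (int di = -1; di <= 1; ++di) {
          int ii2 = std::min(std::max(i + di, 0), n - 1);
          v[k++] = img(ii2, jj);
        }
      }
      std::nth_element(v, v + 4, v + 9);
      out(i, j) = v[4];
    }
  }
  return out;
}

// Scatter orientation-binned magnitudes and return one summed-area table
// per bin (an (n+1) x (m+1) x nbins array).
// [[Rcpp::export]]
NumericVector bin_integrals_c(const NumericMatrix& mag,
                              const IntegerMatrix& bin, const int nbins) {
  const int n = mag.nrow(), m = mag.ncol();
  NumericVector out(Dimension(n + 1, m + 1, nbins));
  const int sz = (n + 1) * (m + 1);
  // accumulate raw values into the shifted position, then integrate
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) {
      const int b = bin(i, j);
      if (b >= 1 && b <= nbins)
        out[(b - 1) * sz + (j + 1) * (n + 1) + (i + 1)] = mag(i, j);
    }
  for (int b = 0; b < nbins; ++b) {
    double* base = &out[b * sz];
    for (int j = 1; j <= m; ++j) {
      double rowsum = 0.0;
      double* col = base + j * (n + 1);
      const double* prev = base + (j - 1) * (n + 1);
      for (int i = 1; i <= n; ++i) {
        rowsum += col[i];
        col[i] = prev[i] + rowsum;
      }
    }
  }
  return out;
}
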
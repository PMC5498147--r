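#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Replicate-border index clamp.
static inline int clampi(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// [[Rcpp::export(name = ".mean_filter_cpp")]]
NumericMatrix mean_filter_cpp(NumericMatrix img, int k) {
  if (k < 1 || k % 2 == 0) stop("kernel size must be a positive odd integer");
  int nr = img.nrow(), nc = img.ncol(), h = k / 2;
  NumericMatrix out(nr, nc);
  double kk = (double)k * (double)k;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      double s = 0.0;
      for (int dc = -h; dc <= h; ++dc) {
        int cc = clampi(c + dc, nc);
        for (int dr = -h; dr <= h; ++dr) {
          s += img(clampi(r + dr, nr), cc);
        }
      }
      out(r, c) = s / kk;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".median_filter_cpp")]]
NumericMatrix median_filter_cpp(NumericMatrix img, int k) {
  if (k < 1 || k % 2 == 0) stop("kernel size must be a positive odd integer");
  int nr = img.nrow(), nc = img.ncol(), h = k / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf(k * k);
  int mid = (k * k) / 2;  // k*k odd -> exact middle element
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int m = 0;
      for (int dc = -h; dc <= h; ++dc) {
        int cc = clampi(c + dc, nc);
        for (int dr = -h; dr <= h; ++dr) {
          buf[m++] = img(clampi(r + dr, nr), cc);
        }
      }
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(r, c) = buf[mid];
    }
  }
  return out;
}

// Separable Gaussian blur, replicate borders; kernel truncated at 3 sigma.
// [[Rcpp::export(name = ".gaussian_blur_cpp")]]
NumericMatrix gaussian_blur_cpp(NumericMatrix img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int h = (int)std::ceil(3.0 * sigma);
  std::vector<double> w(2 * h + 1);
  double s = 0.0;
  for (int i = -h; i <= h; ++i) {
    w[i + h] = std::exp(-0.5 * (double)(i * i) / (sigma * sigma));
    s += w[i + h];
  }
  for (double &x : w) x /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int c = 0; c < nc; ++c)            // vertical pass
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -h; i <= h; ++i) acc += w[i + h] * img(clampi(r + i, nr), c);
      tmp(r, c) = acc;
    }
  for (int c = 0; c < nc; ++c)            // horizontal pass
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -h; i <= h; ++i) acc += w[i + h] * tmp(r, clampi(c + i, nc));
      out(r, c) = acc;
    }
  return out;
}
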
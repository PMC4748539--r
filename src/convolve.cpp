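#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Direct separable Gaussian blur and 3x3 Sobel responses with replicate
// boundary handling. At the kernel sizes used here (PSF sigma < 1 px,
// texture sigma ~ tens of px) direct convolution is far cheaper than an
// FFT round trip, and cohort simulations run thousands of fields.

static inline int clampi(int x, int lo, int hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(NumericMatrix x, double sigma) {
  const int nr = x.nrow(), nc = x.ncol();
  if (sigma <= 0) return clone(x);
  const int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    k[i + radius] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + radius];
  }
  for (double &v : k) v /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j)        // vertical pass (within columns)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -radius; t <= radius; ++t)
        acc += k[t + radius] * x(clampi(i + t, 0, nr - 1), j);
      tmp(i, j) = acc;
    }
  for (int j = 0; j < nc; ++j)        // horizontal pass (across columns)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -radius; t <= radius; ++t)
        acc += k[t + radius] * tmp(i, clampi(j + t, 0, nc - 1));
      out(i, j) = acc;
    }
  return out;
}

// Euclidean Sobel gradient magnitude, replicate boundary; caller
// normalizes by the maximum attainable response.
// [[Rcpp::export]]
NumericMatrix sobel_cpp(NumericMatrix x) {
  const int nr = x.nrow(), nc = x.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    const int jm = clampi(j - 1, 0, nc - 1), jp = clampi(j + 1, 0, nc - 1);
    for (int i = 0; i < nr; ++i) {
      const int im = clampi(i - 1, 0, nr - 1), ip = clampi(i + 1, 0, nr - 1);
      const double gi = (x(ip, jm) + 2.0 * x(ip, j) + x(ip, jp)) -
                        (x(im, jm) + 2.0 * x(im, j) + x(im, jp));
      const double gj = (x(im, jp) + 2.0 * x(i, jp) + x(ip, jp)) -
                        (x(im, jm) + 2.0 * x(i, jm) + x(ip, jm));
      out(i, j) = std::sqrt(gi * gi + gj * gj);
    }
  }
  return out;
}
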
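#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Keys bicubic kernel, a = -0.5 (Catmull-Rom), support [-2, 2]
static inline double cubic_kernel(double x) {
  x = std::fabs(x);
  if (x < 1.0) return (1.5 * x - 2.5) * x * x + 1.0;
  if (x < 2.0) return ((-0.5 * x + 2.5) * x - 4.0) * x + 2.0;
  return 0.0;
}

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Evaluate bicubic interpolant at fractional (r, c), border replicated.
static double bicubic_at(const NumericMatrix &img, double r, double c) {
  const int nr = img.nrow(), nc = img.ncol();
  const int r0 = (int)std::floor(r), c0 = (int)std::floor(c);
  double acc = 0.0, wsum = 0.0;
  for (int i = -1; i <= 2; ++i) {
    const double wr = cubic_kernel(r - (double)(r0 + i));
    if (wr == 0.0) continue;
    const int ri = clampi(r0 + i, 0, nr - 1);
    for (int j = -1; j <= 2; ++j) {
      const double wc = cubic_kernel(c - (double)(c0 + j));
      if (wc == 0.0) continue;
      const int cj = clampi(c0 + j, 0, nc - 1);
      acc += wr * wc * img(ri, cj);
      wsum += wr * wc;
    }
  }
  return acc / wsum;
}

// Resample an image by factors (mag_r, mag_c) with bicubic interpolation.
// Pixel-centre convention: output pixel i samples source (i + 0.5)/m - 0.5.
// [[Rcpp::export]]
NumericMatrix cpp_resample(const NumericMatrix &img, double mag_r, double mag_c) {
  const int nr = img.nrow(), nc = img.ncol();
  const int onr = (int)std::lround(nr * mag_r);
  const int onc = (int)std::lround(nc * mag_c);
  if (onr < 1 || onc < 1)
    stop("resampled image would be smaller than 1x1");
  NumericMatrix out(onr, onc);
  std::vector<double> src_c(onc);
  for (int j = 0; j < onc; ++j) src_c[j] = (j + 0.5) / mag_c - 0.5;
  for (int i = 0; i < onr; ++i) {
    const double sr = (i + 0.5) / mag_r - 0.5;
    for (int j = 0; j < onc; ++j)
      out(i, j) = bicubic_at(img, sr, src_c[j]);
  }
  return out;
}

// Directly compute a size x size crop of the magnified image, centred at
// (center_r, center_c) in *resampled* coordinates (0-based).  Equivalent to
// cpp_resample followed by cropping, but only evaluates the needed pixels.
// Pixels falling outside the resampled image bounds take `fill`.
// [[Rcpp::export]]
NumericMatrix cpp_resample_crop(const NumericMatrix &img, double mag,
                                int center_r, int center_c,
                                int size, double fill) {
  const int nr = img.nrow(), nc = img.ncol();
  const int onr = (int)std::lround(nr * mag);
  const int onc = (int)std::lround(nc * mag);
  if (onr < 1 || onc < 1)
    stop("resampled image would be smaller than 1x1");
  NumericMatrix out(size, size);
  const int half = size / 2;
  for (int k = 0; k < size; ++k) {
    const int rr = center_r - half + k;
    const bool rok = (rr >= 0 && rr < onr);
    const double sr = (rr + 0.5) / mag - 0.5;
    for (int l = 0; l < size; ++l) {
      const int cc = center_c - half + l;
      if (!rok || cc < 0 || cc >= onc) {
        out(k, l) = fill;
      } else {
        out(k, l) = bicubic_at(img, sr, (cc + 0.5) / mag - 0.5);
      }
    }
  }
  return out;
}
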
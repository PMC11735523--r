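// Batched extraction of cubic windows from a 3-D volume with zero padding
// outside the volume bounds.  Windows are returned one per column in R
// array order, ready for the classifier.
#include <Rcpp.h>
using namespace Rcpp;

// Extract w^3 x C feature windows from a 4-D feature map laid out
// (x, y, z, channel) column-major; starts are 1-based spatial indices and
// must be in bounds.
// [[Rcpp::export]]
NumericMatrix cpp_extract_windows4d(NumericVector feat, IntegerVector dims,
                                    IntegerMatrix starts, int w) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2], C = dims[3];
  const int N = starts.nrow();
  const R_xlen_t plane = static_cast<R_xlen_t>(d1) * d2;
  const R_xlen_t volsz = plane * d3;
  const R_xlen_t wsz = static_cast<R_xlen_t>(w) * w * w;
  NumericMatrix out(wsz * C, N);
  for (int n = 0; n < N; ++n) {
    const int s1 = starts(n, 0) - 1, s2 = starts(n, 1) - 1,
              s3 = starts(n, 2) - 1;
    if (s1 < 0 || s2 < 0 || s3 < 0 || s1 + w > d1 || s2 + w > d2 ||
        s3 + w > d3)
      stop("feature window out of bounds");
    double* o = &out(0, n);
    for (int c = 0; c < C; ++c) {
      const double* fc = &feat[c * volsz];
      for (int kz = 0; kz < w; ++kz) {
        for (int ky = 0; ky < w; ++ky) {
          const double* src = fc + (s3 + kz) * plane +
            static_cast<R_xlen_t>(s2 + ky) * d1 + s1;
          double* dst = o + c * wsz + (static_cast<R_xlen_t>(kz) * w + ky) * w;
          std::memcpy(dst, src, sizeof(double) * w);
        }
      }
    }
  }
  return out;
}

// starts: N x 3 matrix of 1-based window start indices (may lie outside the
// volume; out-of-bounds voxels are zero-filled).
// [[Rcpp::export]]
NumericMatrix cpp_extract_windows(NumericVector vol, IntegerVector dims,
                                  IntegerMatrix starts, int w) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const int N = starts.nrow();
  const R_xlen_t plane = static_cast<R_xlen_t>(d1) * d2;
  NumericMatrix out(static_cast<R_xlen_t>(w) * w * w, N);
  for (int n = 0; n < N; ++n) {
    const int s1 = starts(n, 0) - 1, s2 = starts(n, 1) - 1, s3 = starts(n, 2) - 1;
    double* o = &out(0, n);
    for (int kz = 0; kz < w; ++kz) {
      const int iz = s3 + kz;
      if (iz < 0 || iz >= d3) continue;
      for (int ky = 0; ky < w; ++ky) {
        const int iy = s2 + ky;
        if (iy < 0 || iy >= d2) continue;
        const double* src = &vol[iz * plane + static_cast<R_xlen_t>(iy) * d1];
        double* dst = o + (static_cast<R_xlen_t>(kz) * w + ky) * w;
        const int x0 = std::max(0, -s1);
        const int x1 = std::min(w, d1 - s1);
        for (int kx = x0; kx < x1; ++kx) dst[kx] = src[s1 + kx];
      }
    }
  }
  return out;
}
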
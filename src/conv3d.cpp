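// Dense 3-D convolution, max-pooling and their gradients for the patch
// classifier.  Feature maps are stored one sample per column, flattened in
// R array order (x fastest, then y, z, channel).  Convolution is computed
// per sample by im2col followed by a GEMM; kernel weights are stored as a
// (k^3 * C_in) x C_out matrix whose row order matches the im2col row order
// (kx fastest, then ky, kz, input channel).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int out_dim(int d, int k, int stride, int pad) {
  return (d + 2 * pad - k) / stride + 1;
}

// Fill the im2col matrix (k^3*Cin x Sout) for one sample.
static void im2col(const double* x, int d1, int d2, int d3, int C,
                   int k, int stride, int pad, arma::mat& K) {
  const int o1 = out_dim(d1, k, stride, pad);
  const int o2 = out_dim(d2, k, stride, pad);
  const int o3 = out_dim(d3, k, stride, pad);
  const int plane = d1 * d2;
  const int volsz = d1 * d2 * d3;
  K.zeros();
  for (int oz = 0; oz < o3; ++oz) {
    for (int oy = 0; oy < o2; ++oy) {
      for (int ox = 0; ox < o1; ++ox) {
        const int col = ox + o1 * (oy + o2 * oz);
        double* Kc = K.colptr(col);
        const int ix0 = ox * stride - pad;
        const int iy0 = oy * stride - pad;
        const int iz0 = oz * stride - pad;
        for (int c = 0; c < C; ++c) {
          const double* xc = x + c * volsz;
          for (int kz = 0; kz < k; ++kz) {
            const int iz = iz0 + kz;
            if (iz < 0 || iz >= d3) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int iy = iy0 + ky;
              if (iy < 0 || iy >= d2) continue;
              const double* row = xc + iz * plane + iy * d1;
              double* Krow = Kc + c * k * k * k + kz * k * k + ky * k;
              for (int kx = 0; kx < k; ++kx) {
                const int ix = ix0 + kx;
                if (ix < 0 || ix >= d1) continue;
                Krow[kx] = row[ix];
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add the im2col gradient back onto the input gradient of one sample.
static void col2im(const arma::mat& dK, int d1, int d2, int d3, int C,
                   int k, int stride, int pad, double* dx) {
  const int o1 = out_dim(d1, k, stride, pad);
  const int o2 = out_dim(d2, k, stride, pad);
  const int o3 = out_dim(d3, k, stride, pad);
  const int plane = d1 * d2;
  const int volsz = d1 * d2 * d3;
  for (int oz = 0; oz < o3; ++oz) {
    for (int oy = 0; oy < o2; ++oy) {
      for (int ox = 0; ox < o1; ++ox) {
        const int col = ox + o1 * (oy + o2 * oz);
        const double* Kc = dK.colptr(col);
        const int ix0 = ox * stride - pad;
        const int iy0 = oy * stride - pad;
        const int iz0 = oz * stride - pad;
        for (int c = 0; c < C; ++c) {
          double* xc = dx + c * volsz;
          for (int kz = 0; kz < k; ++kz) {
            const int iz = iz0 + kz;
            if (iz < 0 || iz >= d3) continue;
            for (int ky = 0; ky < k; ++ky) {
              const int iy = iy0 + ky;
              if (iy < 0 || iy >= d2) continue;
              double* row = xc + iz * plane + iy * d1;
              const double* Krow = Kc + c * k * k * k + kz * k * k + ky * k;
              for (int kx = 0; kx < k; ++kx) {
                const int ix = ix0 + kx;
                if (ix < 0 || ix >= d1) continue;
                row[ix] += Krow[kx];
              }
            }
          }
        }
      }
    }
  }
}

// Samples are processed in chunks: the im2col matrices of a whole chunk are
// laid side by side and multiplied by the kernel in a single GEMM, which is
// considerably faster than one small GEMM per sample.
// [[Rcpp::export]]
arma::mat cpp_conv3d_fwd(const arma::mat& X, IntegerVector inshape,
                         const arma::mat& W, const arma::vec& b,
                         int k, int stride, int pad) {
  const int d1 = inshape[0], d2 = inshape[1], d3 = inshape[2], C = inshape[3];
  const int o1 = out_dim(d1, k, stride, pad);
  const int o2 = out_dim(d2, k, stride, pad);
  const int o3 = out_dim(d3, k, stride, pad);
  const int Sout = o1 * o2 * o3;
  const int Cout = W.n_cols;
  const arma::uword N = X.n_cols;
  const arma::uword chunk = std::max<arma::uword>(
      1, std::min<arma::uword>(
             N, 8000000 / std::max<arma::uword>(1, W.n_rows * Sout)));
  arma::mat Y(static_cast<arma::uword>(Sout) * Cout, N);
  arma::mat K(W.n_rows, static_cast<arma::uword>(Sout) * chunk);
  for (arma::uword n0 = 0; n0 < N; n0 += chunk) {
    const arma::uword nc = std::min<arma::uword>(chunk, N - n0);
    for (arma::uword j = 0; j < nc; ++j) {
      arma::mat Kj(K.colptr(j * Sout), W.n_rows, Sout, false, true);
      im2col(X.colptr(n0 + j), d1, d2, d3, C, k, stride, pad, Kj);
    }
    const arma::mat Kc(K.memptr(), W.n_rows,
                       static_cast<arma::uword>(Sout) * nc, false, true);
    arma::mat M = Kc.t() * W;                        // (Sout*nc) x Cout
    for (arma::uword j = 0; j < nc; ++j) {
      double* y = Y.colptr(n0 + j);
      for (int c = 0; c < Cout; ++c) {
        const double* src = M.colptr(c) + j * Sout;
        double* dst = y + static_cast<arma::uword>(c) * Sout;
        const double bc = b[c];
        for (int s = 0; s < Sout; ++s) dst[s] = src[s] + bc;
      }
    }
  }
  return Y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(const arma::mat& X, const arma::mat& dY,
                    IntegerVector inshape, const arma::mat& W,
                    int k, int stride, int pad) {
  const int d1 = inshape[0], d2 = inshape[1], d3 = inshape[2], C = inshape[3];
  const int o1 = out_dim(d1, k, stride, pad);
  const int o2 = out_dim(d2, k, stride, pad);
  const int o3 = out_dim(d3, k, stride, pad);
  const int Sout = o1 * o2 * o3;
  const int Cout = W.n_cols;
  const arma::uword N = X.n_cols;
  arma::mat dX(X.n_rows, N, arma::fill::zeros);
  arma::mat dW(W.n_rows, W.n_cols, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat K(W.n_rows, Sout);
  for (arma::uword n = 0; n < N; ++n) {
    im2col(X.colptr(n), d1, d2, d3, C, k, stride, pad, K);
    const arma::mat dM(const_cast<double*>(dY.colptr(n)), Sout, Cout,
                       false, true);
    dW += K * dM;
    db += arma::sum(dM, 0).t();
    arma::mat dK = W * dM.t();          // (k^3 Cin) x Sout
    col2im(dK, d1, d2, d3, C, k, stride, pad, dX.colptr(n));
  }
  return List::create(_["dx"] = dX, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::mat& X, IntegerVector inshape,
                     int k, int stride, int pad) {
  const int d1 = inshape[0], d2 = inshape[1], d3 = inshape[2], C = inshape[3];
  const int o1 = out_dim(d1, k, stride, pad);
  const int o2 = out_dim(d2, k, stride, pad);
  const int o3 = out_dim(d3, k, stride, pad);
  const int Sout = o1 * o2 * o3;
  const int plane = d1 * d2;
  const int volsz = d1 * d2 * d3;
  const arma::uword N = X.n_cols;
  arma::mat Y(static_cast<arma::uword>(Sout) * C, N);
  IntegerMatrix arg(Sout * C, N);
  for (arma::uword n = 0; n < N; ++n) {
    const double* x = X.colptr(n);
    double* y = Y.colptr(n);
    for (int c = 0; c < C; ++c) {
      const double* xc = x + c * volsz;
      for (int oz = 0; oz < o3; ++oz) {
        for (int oy = 0; oy < o2; ++oy) {
          for (int ox = 0; ox < o1; ++ox) {
            double best = -std::numeric_limits<double>::infinity();
            int bidx = -1;
            for (int kz = 0; kz < k; ++kz) {
              const int iz = oz * stride - pad + kz;
              if (iz < 0 || iz >= d3) continue;
              for (int ky = 0; ky < k; ++ky) {
                const int iy = oy * stride - pad + ky;
                if (iy < 0 || iy >= d2) continue;
                for (int kx = 0; kx < k; ++kx) {
                  const int ix = ox * stride - pad + kx;
                  if (ix < 0 || ix >= d1) continue;
                  const int idx = c * volsz + iz * plane + iy * d1 + ix;
                  if (xc[iz * plane + iy * d1 + ix] > best) {
                    best = xc[iz * plane + iy * d1 + ix];
                    bidx = idx;
                  }
                }
              }
            }
            const int o = c * Sout + ox + o1 * (oy + o2 * oz);
            y[o] = best;
            arg(o, n) = bidx;
          }
        }
      }
    }
  }
  return List::create(_["y"] = Y, _["argmax"] = arg);
}

// [[Rcpp::export]]
arma::mat cpp_maxpool_bwd(const arma::mat& dY, IntegerMatrix argmax,
                          int insize) {
  const arma::uword N = dY.n_cols;
  arma::mat dX(insize, N, arma::fill::zeros);
  for (arma::uword n = 0; n < N; ++n) {
    double* dx = dX.colptr(n);
    const double* dy = dY.colptr(n);
    for (int i = 0; i < argmax.nrow(); ++i) {
      dx[argmax(i, n)] += dy[i];
    }
  }
  return dX;
}
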
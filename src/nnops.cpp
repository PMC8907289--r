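// Low-level 3-D CNN primitives: im2col/col2im for 3x3x3 same-padded
// convolution and 2x2x2 max-pooling, batched over samples.
//
// Layout convention (matches R): an activation batch is a C x (N*B) matrix
// where N = dx*dy*dz voxels per sample, B = samples, and the voxel linear
// index within a sample is x + dx*(y + dy*z) (x fastest, 0-based), i.e.
// column-major R array order. Sample blocks are contiguous in columns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Expand a batch into overlapping 3x3x3 patches with zero padding 1.
// X: C x (N*B)  ->  (C*27) x (N*B); patch row order: channel fastest,
// then kernel offset (ox fastest, then oy, oz).
// [[Rcpp::export]]
arma::mat im2col3d(const arma::mat& X, const arma::ivec& dims, int nb) {
  const int C = X.n_rows;
  const int dx = dims[0], dy = dims[1], dz = dims[2];
  const int N = dx * dy * dz;
  arma::mat K(C * 27, (arma::uword)N * nb, arma::fill::zeros);
  for (int b = 0; b < nb; ++b) {
    const arma::uword base = (arma::uword)b * N;
    for (int oz = -1; oz <= 1; ++oz)
      for (int oy = -1; oy <= 1; ++oy)
        for (int ox = -1; ox <= 1; ++ox) {
          const int krow = ((oz + 1) * 3 + (oy + 1)) * 3 + (ox + 1);
          for (int z = 0; z < dz; ++z) {
            const int sz = z + oz;
            if (sz < 0 || sz >= dz) continue;
            for (int y = 0; y < dy; ++y) {
              const int sy = y + oy;
              if (sy < 0 || sy >= dy) continue;
              const int x0 = std::max(0, -ox), x1 = std::min(dx, dx - ox);
              for (int x = x0; x < x1; ++x) {
                const int sx = x + ox;
                const arma::uword dst = base + x + (arma::uword)dx * (y + (arma::uword)dy * z);
                const arma::uword src = base + sx + (arma::uword)dx * (sy + (arma::uword)dy * sz);
                for (int c = 0; c < C; ++c)
                  K(krow * C + c, dst) = X(c, src);
              }
            }
          }
        }
  }
  return K;
}

// Adjoint of im2col3d: scatter patch-gradients back onto the input grid.
// G: (C*27) x (N*B)  ->  C x (N*B)
// [[Rcpp::export]]
arma::mat col2im3d(const arma::mat& G, int C, const arma::ivec& dims, int nb) {
  const int dx = dims[0], dy = dims[1], dz = dims[2];
  const int N = dx * dy * dz;
  arma::mat X(C, (arma::uword)N * nb, arma::fill::zeros);
  for (int b = 0; b < nb; ++b) {
    const arma::uword base = (arma::uword)b * N;
    for (int oz = -1; oz <= 1; ++oz)
      for (int oy = -1; oy <= 1; ++oy)
        for (int ox = -1; ox <= 1; ++ox) {
          const int krow = ((oz + 1) * 3 + (oy + 1)) * 3 + (ox + 1);
          for (int z = 0; z < dz; ++z) {
            const int sz = z + oz;
            if (sz < 0 || sz >= dz) continue;
            for (int y = 0; y < dy; ++y) {
              const int sy = y + oy;
              if (sy < 0 || sy >= dy) continue;
              const int x0 = std::max(0, -ox), x1 = std::min(dx, dx - ox);
              for (int x = x0; x < x1; ++x) {
                const int sx = x + ox;
                const arma::uword dst = base + x + (arma::uword)dx * (y + (arma::uword)dy * z);
                const arma::uword src = base + sx + (arma::uword)dx * (sy + (arma::uword)dy * sz);
                for (int c = 0; c < C; ++c)
                  X(c, src) += G(krow * C + c, dst);
              }
            }
          }
        }
  }
  return X;
}

// 2x2x2 max-pooling, stride 2. Input dims must be even.
// Returns pooled values (C x (N/8 * B)) and 1-based argmax column indices
// into the input batch matrix (same shape as pooled).
// [[Rcpp::export]]
List maxpool3d_fwd(const arma::mat& X, const arma::ivec& dims, int nb) {
  const int C = X.n_rows;
  const int dx = dims[0], dy = dims[1], dz = dims[2];
  const int px = dx / 2, py = dy / 2, pz = dz / 2;
  const int N = dx * dy * dz, P = px * py * pz;
  arma::mat Y(C, (arma::uword)P * nb);
  arma::umat A(C, (arma::uword)P * nb);
  for (int b = 0; b < nb; ++b) {
    const arma::uword ibase = (arma::uword)b * N;
    const arma::uword obase = (arma::uword)b * P;
    for (int z = 0; z < pz; ++z)
      for (int y = 0; y < py; ++y)
        for (int x = 0; x < px; ++x) {
          const arma::uword oc = obase + x + (arma::uword)px * (y + (arma::uword)py * z);
          for (int c = 0; c < C; ++c) {
            double best = -std::numeric_limits<double>::infinity();
            arma::uword bidx = 0;
            for (int kz = 0; kz < 2; ++kz)
              for (int ky = 0; ky < 2; ++ky)
                for (int kx = 0; kx < 2; ++kx) {
                  const arma::uword ic = ibase + (2 * x + kx) +
                    (arma::uword)dx * ((2 * y + ky) + (arma::uword)dy * (2 * z + kz));
                  const double v = X(c, ic);
                  if (v > best) { best = v; bidx = ic; }
                }
            Y(c, oc) = best;
            A(c, oc) = bidx + 1;  // 1-based for R
          }
        }
  }
  return List::create(_["values"] = Y, _["argmax"] = A);
}

// Backward pass of 2x2x2 max-pooling: route gradients to argmax positions.
// [[Rcpp::export]]
arma::mat maxpool3d_bwd(const arma::mat& dY, const arma::umat& argmax,
                        const arma::ivec& dims, int nb) {
  const int C = dY.n_rows;
  const int N = dims[0] * dims[1] * dims[2];
  arma::mat dX(C, (arma::uword)N * nb, arma::fill::zeros);
  for (arma::uword j = 0; j < dY.n_cols; ++j)
    for (int c = 0; c < C; ++c)
      dX(c, argmax(c, j) - 1) += dY(c, j);
  return dX;
}
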
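// Low-level kernels for the 3D patch network: im2col/col2im for 3x3x3
// "same" convolutions and 2x2x2 max pooling. Feature maps are matrices
// with one row per voxel (x fastest, as in R arrays) and one column per
// channel; the convolution itself is a BLAS matrix product done in R on
// the im2col expansion.

#include <Rcpp.h>
#include <cstring>
#include <limits>

using namespace Rcpp;

// Column layout of the expansion: column k * cin + c holds channel c
// sampled at neighbourhood offset k, where k enumerates (dx, dy, dz) in
// {-1,0,1}^3 with dx fastest. Out-of-grid samples are zero.
// [[Rcpp::export]]
NumericMatrix cn_im2col(const NumericMatrix& X, int d1, int d2, int d3) {
  const int n = d1 * d2 * d3;
  const int cin = X.ncol();
  if (X.nrow() != n) stop("cn_im2col: row count does not match dims");
  NumericMatrix out(n, 27 * cin);
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        const int z0 = std::max(0, -dz), z1 = std::min(d3, d3 - dz);
        const int y0 = std::max(0, -dy), y1 = std::min(d2, d2 - dy);
        const int x0 = std::max(0, -dx), x1 = std::min(d1, d1 - dx);
        if (x1 <= x0) continue;
        for (int c = 0; c < cin; ++c) {
          const double* src = &X(0, c);
          double* dst = &out(0, k * cin + c);
          for (int z = z0; z < z1; ++z) {
            for (int y = y0; y < y1; ++y) {
              const int srow = (x0 + dx) + d1 * ((y + dy) + d2 * (z + dz));
              const int drow = x0 + d1 * (y + d2 * z);
              std::memcpy(dst + drow, src + srow, sizeof(double) * (x1 - x0));
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of cn_im2col: scatter-add the expanded columns back to voxels.
// [[Rcpp::export]]
NumericMatrix cn_col2im(const NumericMatrix& C, int d1, int d2, int d3, int cin) {
  const int n = d1 * d2 * d3;
  if (C.nrow() != n || C.ncol() != 27 * cin) stop("cn_col2im: shape mismatch");
  NumericMatrix out(n, cin);
  int k = 0;
  for (int dz = -1; dz <= 1; ++dz) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx, ++k) {
        const int z0 = std::max(0, -dz), z1 = std::min(d3, d3 - dz);
        const int y0 = std::max(0, -dy), y1 = std::min(d2, d2 - dy);
        const int x0 = std::max(0, -dx), x1 = std::min(d1, d1 - dx);
        if (x1 <= x0) continue;
        for (int c = 0; c < cin; ++c) {
          const double* src = &C(0, k * cin + c);
          double* dst = &out(0, c);
          for (int z = z0; z < z1; ++z) {
            for (int y = y0; y < y1; ++y) {
              const int drow = (x0 + dx) + d1 * ((y + dy) + d2 * (z + dz));
              const int srow = x0 + d1 * (y + d2 * z);
              const double* s = src + srow;
              double* d = dst + drow;
              for (int x = 0; x < x1 - x0; ++x) d[x] += s[x];
            }
          }
        }
      }
    }
  }
  return out;
}

// 2x2x2 max pooling (dims must be even). Returns the pooled map and the
// 1-based row index of each winning voxel for the backward pass.
// [[Rcpp::export]]
List cn_maxpool(const NumericMatrix& X, int d1, int d2, int d3) {
  if (d1 % 2 || d2 % 2 || d3 % 2) stop("cn_maxpool: dims must be even");
  const int cin = X.ncol();
  const int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  const int no = o1 * o2 * o3;
  NumericMatrix Y(no, cin);
  IntegerMatrix idx(no, cin);
  for (int c = 0; c < cin; ++c) {
    const double* src = &X(0, c);
    for (int z = 0; z < o3; ++z) {
      for (int y = 0; y < o2; ++y) {
        for (int x = 0; x < o1; ++x) {
          double best = -std::numeric_limits<double>::infinity();
          int besti = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const int r = (2 * x + dx) + d1 * ((2 * y + dy) + d2 * (2 * z + dz));
                if (src[r] > best) { best = src[r]; besti = r; }
              }
          const int orow = x + o1 * (y + o2 * z);
          Y(orow, c) = best;
          idx(orow, c) = besti + 1;  // 1-based for R
        }
      }
    }
  }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cn_maxpool_bwd(const NumericMatrix& dY, const IntegerMatrix& idx,
                             int n) {
  const int cin = dY.ncol();
  NumericMatrix dX(n, cin);
  for (int c = 0; c < cin; ++c) {
    for (int r = 0; r < dY.nrow(); ++r) {
      dX(idx(r, c) - 1, c) += dY(r, c);
    }
  }
  return dX;
}
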
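// Convolution and pooling kernels for the segmentation network.
//
// Layout conventions (column-major R arrays):
//   feature maps : dim (X, Y, Z, C)       -- Z == 1 for 2D models
//   conv weights : dim (kx, ky, kz, Cin, Cout), "same" zero padding,
//                  pad = (k - 1) / 2 per axis (odd kernels only)
// im2col column order matches the column-major flattening of
// (kx, ky, kz, Cin), so the weight tensor reshapes directly to a
// (K x Cout) matrix with K = kx*ky*kz*Cin.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static IntegerVector dims_of(const NumericVector& x) {
  RObject d = x.attr("dim");
  if (d.isNULL()) stop("input must be a dim-ed array");
  return as<IntegerVector>(d);
}

// Fill the im2col matrix: rows = voxels (column-major over X,Y,Z),
// cols = (dx, dy, dz, cin) column-major.
static void im2col_fill(const double* x, int X, int Y, int Z, int Ci,
                        int kx, int ky, int kz, arma::mat& cols) {
  const int px = (kx - 1) / 2, py = (ky - 1) / 2, pz = (kz - 1) / 2;
  const R_xlen_t plane = (R_xlen_t)X * Y;
  const R_xlen_t chan = plane * Z;
  int col = 0;
  for (int ci = 0; ci < Ci; ++ci) {
    for (int dz = 0; dz < kz; ++dz) {
      for (int dy = 0; dy < ky; ++dy) {
        for (int dx = 0; dx < kx; ++dx, ++col) {
          double* dst = cols.colptr(col);
          const int oz = dz - pz, oy = dy - py, ox = dx - px;
          for (int iz = 0; iz < Z; ++iz) {
            const int sz = iz + oz;
            if (sz < 0 || sz >= Z) {
              std::fill(dst + iz * plane, dst + (iz + 1) * plane, 0.0);
              continue;
            }
            for (int iy = 0; iy < Y; ++iy) {
              const int sy = iy + oy;
              double* row = dst + iz * plane + (R_xlen_t)iy * X;
              if (sy < 0 || sy >= Y) {
                std::fill(row, row + X, 0.0);
                continue;
              }
              const double* src =
                x + ci * chan + (R_xlen_t)sz * plane + (R_xlen_t)sy * X;
              // shifted copy along x with zero borders
              int lo = std::max(0, -ox), hi = std::min(X, X - ox);
              for (int ix = 0; ix < lo; ++ix) row[ix] = 0.0;
              for (int ix = lo; ix < hi; ++ix) row[ix] = src[ix + ox];
              for (int ix = hi; ix < X; ++ix) row[ix] = 0.0;
            }
          }
        }
      }
    }
  }
}

// Returns list(out, cols); cols (the im2col matrix) is reused by the
// weight-gradient pass and is NULL for 1x1 convolutions, which skip im2col
// entirely (the input matrix itself serves as cols).
// [[Rcpp::export(name = ".convForward")]]
List conv_forward(NumericVector x, NumericVector w, NumericVector b,
                  bool keepCols) {
  IntegerVector xd = dims_of(x), wd = dims_of(w);
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3];
  const int kx = wd[0], ky = wd[1], kz = wd[2], Co = wd[4];
  if (wd[3] != Ci) stop("conv: input has %d channels, weights expect %d", Ci, wd[3]);
  const R_xlen_t nvox = (R_xlen_t)X * Y * Z;
  const int K = kx * ky * kz * Ci;
  arma::mat W(w.begin(), K, Co, false, true);
  arma::mat out;
  NumericMatrix colsR;
  bool hasCols = false;
  if (K == Ci) {  // 1x1 kernel: input is already the im2col matrix
    arma::mat xm(x.begin(), nvox, Ci, false, true);
    out = xm * W;
  } else {
    colsR = NumericMatrix((int)nvox, K);
    arma::mat cols(colsR.begin(), nvox, K, false, true);
    im2col_fill(x.begin(), X, Y, Z, Ci, kx, ky, kz, cols);
    out = cols * W;
    hasCols = keepCols;
  }
  for (int co = 0; co < Co; ++co) out.col(co) += b[co];
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(X, Y, Z, Co);
  return List::create(_["out"] = res,
                      _["cols"] = hasCols ? (SEXP)colsR : R_NilValue);
}

// [[Rcpp::export(name = ".convBackwardInput")]]
NumericVector conv_backward_input(NumericVector dy, NumericVector w) {
  IntegerVector yd = dims_of(dy), wd = dims_of(w);
  const int X = yd[0], Y = yd[1], Z = yd[2], Co = yd[3];
  const int kx = wd[0], ky = wd[1], kz = wd[2], Ci = wd[3];
  const int px = (kx - 1) / 2, py = (ky - 1) / 2, pz = (kz - 1) / 2;
  const R_xlen_t nvox = (R_xlen_t)X * Y * Z;
  const int K = kx * ky * kz * Ci;
  arma::mat dY(dy.begin(), nvox, Co, false, true);
  arma::mat W(w.begin(), K, Co, false, true);
  if (K == Ci) {  // 1x1 kernel: no scatter needed
    arma::mat dxm = dY * W.t();
    NumericVector dx1(dxm.begin(), dxm.end());
    dx1.attr("dim") = IntegerVector::create(X, Y, Z, Ci);
    return dx1;
  }
  arma::mat dcols = dY * W.t();  // nvox x K
  NumericVector dx((R_xlen_t)X * Y * Z * Ci);
  double* out = dx.begin();
  const R_xlen_t plane = (R_xlen_t)X * Y;
  const R_xlen_t chan = plane * Z;
  int col = 0;
  for (int ci = 0; ci < Ci; ++ci) {
    for (int dz = 0; dz < kz; ++dz) {
      for (int dyk = 0; dyk < ky; ++dyk) {
        for (int dxk = 0; dxk < kx; ++dxk, ++col) {
          const double* src = dcols.colptr(col);
          const int oz = dz - pz, oy = dyk - py, ox = dxk - px;
          for (int iz = 0; iz < Z; ++iz) {
            const int sz = iz + oz;
            if (sz < 0 || sz >= Z) continue;
            for (int iy = 0; iy < Y; ++iy) {
              const int sy = iy + oy;
              if (sy < 0 || sy >= Y) continue;
              const double* s = src + iz * plane + (R_xlen_t)iy * X;
              double* d = out + ci * chan + (R_xlen_t)sz * plane + (R_xlen_t)sy * X;
              int lo = std::max(0, -ox), hi = std::min(X, X - ox);
              for (int ix = lo; ix < hi; ++ix) d[ix + ox] += s[ix];
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(X, Y, Z, Ci);
  return dx;
}

// `cachedCols`: the cols matrix from the forward pass (or NULL to rebuild).
// [[Rcpp::export(name = ".convBackwardWeight")]]
List conv_backward_weight(NumericVector x, NumericVector dy,
                          IntegerVector kdim, SEXP cachedCols) {
  IntegerVector xd = dims_of(x), yd = dims_of(dy);
  const int X = xd[0], Y = xd[1], Z = xd[2], Ci = xd[3], Co = yd[3];
  const int kx = kdim[0], ky = kdim[1], kz = kdim[2];
  const R_xlen_t nvox = (R_xlen_t)X * Y * Z;
  const int K = kx * ky * kz * Ci;
  arma::mat dY(dy.begin(), nvox, Co, false, true);
  arma::mat dW;
  if (K == Ci) {
    arma::mat xm(x.begin(), nvox, Ci, false, true);
    dW = xm.t() * dY;
  } else if (cachedCols != R_NilValue) {
    NumericMatrix colsR(cachedCols);
    arma::mat cols(colsR.begin(), nvox, K, false, true);
    dW = cols.t() * dY;
  } else {
    arma::mat cols(nvox, K);
    im2col_fill(x.begin(), X, Y, Z, Ci, kx, ky, kz, cols);
    dW = cols.t() * dY;
  }
  NumericVector dw(dW.begin(), dW.end());
  dw.attr("dim") = IntegerVector::create(kx, ky, kz, Ci, Co);
  NumericVector db(Co);
  for (int co = 0; co < Co; ++co) db[co] = arma::accu(dY.col(co));
  return List::create(_["dw"] = dw, _["db"] = db);
}

// Strided max pooling (window == stride, no padding; dims must divide).
// [[Rcpp::export(name = ".maxPoolForward")]]
List maxpool_forward(NumericVector x, IntegerVector pool) {
  IntegerVector xd = dims_of(x);
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int px = pool[0], py = pool[1], pz = pool[2];
  if (X % px || Y % py || Z % pz) stop("pooling: spatial dims not divisible");
  const int OX = X / px, OY = Y / py, OZ = Z / pz;
  const R_xlen_t plane = (R_xlen_t)X * Y, chan = plane * Z;
  NumericVector out((R_xlen_t)OX * OY * OZ * C);
  NumericVector amax((R_xlen_t)OX * OY * OZ * C);  // 0-based linear index into x
  const double* in = x.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int oz = 0; oz < OZ; ++oz)
      for (int oy = 0; oy < OY; ++oy)
        for (int ox = 0; ox < OX; ++ox, ++o) {
          double best = -std::numeric_limits<double>::infinity();
          R_xlen_t bi = 0;
          for (int dz = 0; dz < pz; ++dz)
            for (int dy = 0; dy < py; ++dy)
              for (int dx = 0; dx < px; ++dx) {
                R_xlen_t idx = (R_xlen_t)c * chan + (R_xlen_t)(oz * pz + dz) * plane +
                               (R_xlen_t)(oy * py + dy) * X + (ox * px + dx);
                if (in[idx] > best) { best = in[idx]; bi = idx; }
              }
          out[o] = best;
          amax[o] = (double)bi;
        }
  out.attr("dim") = IntegerVector::create(OX, OY, OZ, C);
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".maxPoolBackward")]]
NumericVector maxpool_backward(NumericVector dy, NumericVector argmax,
                               IntegerVector xdim) {
  NumericVector dx((R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3]);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[(R_xlen_t)argmax[i]] += dy[i];
  dx.attr("dim") = xdim;
  return dx;
}

// Size-preserving pooling for the fusion branch: window of 2 along each
// pooled axis starting at the voxel ("same" padding for an even kernel,
// stride 1); windows are clamped at the far border. type: 0 = average
// (count excludes padding), 1 = max. Returns argmax for the max variant.
// [[Rcpp::export(name = ".poolK2S1Forward")]]
List pool_k2s1_forward(NumericVector x, IntegerVector pooled, int type) {
  IntegerVector xd = dims_of(x);
  const int X = xd[0], Y = xd[1], Z = xd[2], C = xd[3];
  const int wx = pooled[0] ? 2 : 1, wy = pooled[1] ? 2 : 1, wz = pooled[2] ? 2 : 1;
  const R_xlen_t plane = (R_xlen_t)X * Y, chan = plane * Z;
  NumericVector out(x.size()), amax(type == 1 ? x.size() : 0);
  const double* in = x.begin();
  R_xlen_t o = 0;
  for (int c = 0; c < C; ++c)
    for (int iz = 0; iz < Z; ++iz)
      for (int iy = 0; iy < Y; ++iy)
        for (int ix = 0; ix < X; ++ix, ++o) {
          double acc = (type == 1) ? -std::numeric_limits<double>::infinity() : 0.0;
          int n = 0;
          R_xlen_t bi = 0;
          for (int dz = 0; dz < wz && iz + dz < Z; ++dz)
            for (int dy = 0; dy < wy && iy + dy < Y; ++dy)
              for (int dx = 0; dx < wx && ix + dx < X; ++dx) {
                R_xlen_t idx = (R_xlen_t)c * chan + (R_xlen_t)(iz + dz) * plane +
                               (R_xlen_t)(iy + dy) * X + (ix + dx);
                if (type == 1) {
                  if (in[idx] > acc) { acc = in[idx]; bi = idx; }
                } else acc += in[idx];
                ++n;
              }
          if (type == 1) { out[o] = acc; amax[o] = (double)bi; }
          else out[o] = acc / n;
        }
  out.attr("dim") = xd;
  return List::create(_["out"] = out, _["argmax"] = amax);
}

// [[Rcpp::export(name = ".poolK2S1Backward")]]
NumericVector pool_k2s1_backward(NumericVector dy, NumericVector argmax,
                                 IntegerVector xdim, IntegerVector pooled,
                                 int type) {
  const int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3];
  NumericVector dx(dy.size());
  if (type == 1) {
    for (R_xlen_t i = 0; i < dy.size(); ++i) dx[(R_xlen_t)argmax[i]] += dy[i];
  } else {
    const int wx = pooled[0] ? 2 : 1, wy = pooled[1] ? 2 : 1, wz = pooled[2] ? 2 : 1;
    const R_xlen_t plane = (R_xlen_t)X * Y, chan = plane * Z;
    const double* g = dy.begin();
    R_xlen_t o = 0;
    for (int c = 0; c < C; ++c)
      for (int iz = 0; iz < Z; ++iz)
        for (int iy = 0; iy < Y; ++iy)
          for (int ix = 0; ix < X; ++ix, ++o) {
            int nx = std::min(wx, X - ix), ny = std::min(wy, Y - iy),
                nz = std::min(wz, Z - iz);
            double share = g[o] / (nx * ny * nz);
            for (int dz = 0; dz < nz; ++dz)
              for (int dy2 = 0; dy2 < ny; ++dy2)
                for (int dx2 = 0; dx2 < nx; ++dx2)
                  dx[(R_xlen_t)c * chan + (R_xlen_t)(iz + dz) * plane +
                     (R_xlen_t)(iy + dy2) * X + (ix + dx2)] += share;
          }
  }
  dx.attr("dim") = xdim;
  return dx;
}
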
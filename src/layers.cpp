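// Pooling kernels for the SFCN-style encoder.
// Array layout is R column-major (X, Y, Z, C, N): x fastest, sample slowest.

#include <Rcpp.h>
using namespace Rcpp;

static void dims5(const NumericVector& a, int& X, int& Y, int& Z, int& C, int& N) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 5) stop("expected a 5-d array (X, Y, Z, C, N)");
  X = d[0]; Y = d[1]; Z = d[2]; C = d[3]; N = d[4];
}

// 2x2x2 max pooling, stride 2, floor mode; an extent of 1 passes through
// unchanged.  Returns pooled values and 0-based argmax indices into x.
// [[Rcpp::export]]
List maxpool3d_fw(NumericVector x) {
  int X, Y, Z, C, N;
  dims5(x, X, Y, Z, C, N);
  int OX = X == 1 ? 1 : X / 2, OY = Y == 1 ? 1 : Y / 2, OZ = Z == 1 ? 1 : Z / 2;
  int wx = X == 1 ? 1 : 2, wy = Y == 1 ? 1 : 2, wz = Z == 1 ? 1 : 2;
  R_xlen_t sv = (R_xlen_t)X * Y * Z, ov = (R_xlen_t)OX * OY * OZ;
  NumericVector y(ov * C * N);
  y.attr("dim") = IntegerVector::create(OX, OY, OZ, C, N);
  IntegerVector idx(ov * C * N);
  double* yp = REAL(y);
  int* ip = INTEGER(idx);
  const double* xp = REAL(x);

  for (int n = 0; n < N; n++)
  for (int c = 0; c < C; c++) {
    R_xlen_t xb = sv * (c + (R_xlen_t)C * n);
    R_xlen_t yb = ov * (c + (R_xlen_t)C * n);
    for (int oz = 0; oz < OZ; oz++)
    for (int oy = 0; oy < OY; oy++)
    for (int ox = 0; ox < OX; ox++) {
      double best = R_NegInf;
      R_xlen_t bidx = -1;
      for (int az = 0; az < wz; az++)
      for (int ay = 0; ay < wy; ay++)
      for (int ax = 0; ax < wx; ax++) {
        int iz = wz == 1 ? 0 : 2 * oz + az;
        int iy = wy == 1 ? 0 : 2 * oy + ay;
        int ix = wx == 1 ? 0 : 2 * ox + ax;
        R_xlen_t pos = xb + ix + (R_xlen_t)X * (iy + (R_xlen_t)Y * iz);
        double v = xp[pos];
        if (v > best) { best = v; bidx = pos; }
      }
      R_xlen_t opos = yb + ox + (R_xlen_t)OX * (oy + (R_xlen_t)OY * oz);
      yp[opos] = best;
      ip[opos] = (int)bidx;
    }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bw(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  R_xlen_t xn = 1;
  for (int i = 0; i < xdim.size(); i++) xn *= xdim[i];
  NumericVector gx(xn);
  gx.attr("dim") = xdim;
  double* gxp = REAL(gx);
  const double* gyp = REAL(gy);
  const int* ip = INTEGER(idx);
  R_xlen_t m = gy.size();
  for (R_xlen_t t = 0; t < m; t++) gxp[ip[t]] += gyp[t];
  return gx;
}

// 2x2x2 average pooling, stride 2, floor mode.  Callers skip this layer
// entirely when any spatial extent is < 2, so windows are always full.
// [[Rcpp::export]]
NumericVector avgpool3d_fw(NumericVector x) {
  int X, Y, Z, C, N;
  dims5(x, X, Y, Z, C, N);
  int OX = X / 2, OY = Y / 2, OZ = Z / 2;
  R_xlen_t sv = (R_xlen_t)X * Y * Z, ov = (R_xlen_t)OX * OY * OZ;
  NumericVector y(ov * C * N);
  y.attr("dim") = IntegerVector::create(OX, OY, OZ, C, N);
  double* yp = REAL(y);
  const double* xp = REAL(x);
  for (int n = 0; n < N; n++)
  for (int c = 0; c < C; c++) {
    R_xlen_t xb = sv * (c + (R_xlen_t)C * n);
    R_xlen_t yb = ov * (c + (R_xlen_t)C * n);
    for (int oz = 0; oz < OZ; oz++)
    for (int oy = 0; oy < OY; oy++)
    for (int ox = 0; ox < OX; ox++) {
      double acc = 0.0;
      for (int az = 0; az < 2; az++)
      for (int ay = 0; ay < 2; ay++)
      for (int ax = 0; ax < 2; ax++) {
        acc += xp[xb + (2 * ox + ax) + (R_xlen_t)X * ((2 * oy + ay) + (R_xlen_t)Y * (2 * oz + az))];
      }
      yp[yb + ox + (R_xlen_t)OX * (oy + (R_xlen_t)OY * oz)] = acc / 8.0;
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool3d_bw(NumericVector gy, IntegerVector xdim) {
  int X = xdim[0], Y = xdim[1], Z = xdim[2], C = xdim[3], N = xdim[4];
  int OX = X / 2, OY = Y / 2, OZ = Z / 2;
  R_xlen_t sv = (R_xlen_t)X * Y * Z, ov = (R_xlen_t)OX * OY * OZ;
  NumericVector gx(sv * C * N);
  gx.attr("dim") = xdim;
  double* gxp = REAL(gx);
  const double* gyp = REAL(gy);
  for (int n = 0; n < N; n++)
  for (int c = 0; c < C; c++) {
    R_xlen_t xb = sv * (c + (R_xlen_t)C * n);
    R_xlen_t yb = ov * (c + (R_xlen_t)C * n);
    for (int oz = 0; oz < OZ; oz++)
    for (int oy = 0; oy < OY; oy++)
    for (int ox = 0; ox < OX; ox++) {
      double g = gyp[yb + ox + (R_xlen_t)OX * (oy + (R_xlen_t)OY * oz)] / 8.0;
      for (int az = 0; az < 2; az++)
      for (int ay = 0; ay < 2; ay++)
      for (int ax = 0; ax < 2; ax++) {
        gxp[xb + (2 * ox + ax) + (R_xlen_t)X * ((2 * oy + ay) + (R_xlen_t)Y * (2 * oz + az))] += g;
      }
    }
  }
  return gx;
}

// y[i] = x[i] * a[ch] + b[ch] where ch = (i / V) %% C; used by batch norm.
// [[Rcpp::export]]
NumericVector channel_affine(NumericVector x, NumericVector a, NumericVector b,
                             int V, int C) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  const double* xp = REAL(x);
  double* yp = REAL(y);
  const double* ap = REAL(a);
  const double* bp = REAL(b);
  R_xlen_t ncol = x.size() / V;
  for (R_xlen_t col = 0; col < ncol; col++) {
    int ch = (int)(col % C);
    double av = ap[ch], bv = bp[ch];
    const double* xr = xp + (R_xlen_t)col * V;
    double* yr = yp + (R_xlen_t)col * V;
    for (int i = 0; i < V; i++) yr[i] = xr[i] * av + bv;
  }
  return y;
}

// Per-channel sums of x and of x*y (y may be the same vector as x).
// [[Rcpp::export]]
List channel_sums(NumericVector x, NumericVector y, int V, int C) {
  NumericVector sx(C), sxy(C);
  const double* xp = REAL(x);
  const double* yp = REAL(y);
  R_xlen_t ncol = x.size() / V;
  for (R_xlen_t col = 0; col < ncol; col++) {
    int ch = (int)(col % C);
    const double* xr = xp + (R_xlen_t)col * V;
    const double* yr = yp + (R_xlen_t)col * V;
    double a = 0.0, b = 0.0;
    for (int i = 0; i < V; i++) { a += xr[i]; b += xr[i] * yr[i]; }
    sx[ch] += a;
    sxy[ch] += b;
  }
  return List::create(_["sum"] = sx, _["sum_prod"] = sxy);
}
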
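// im2col-based 3D convolution ("same" padding) with BLAS-backed matrix
// products.  Patch matrix layout: A is (V*N) x (K^3*Ci) with column
// c = offset + K^3*ci, so the flattened weight array (K,K,K,Ci,Co) maps
// directly onto the (K^3*Ci) x Co right-hand factor.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void dims5c(const NumericVector& a, int& X, int& Y, int& Z, int& C, int& N) {
  IntegerVector d = a.attr("dim");
  if (d.size() != 5) stop("expected a 5-d array (X, Y, Z, C, N)");
  X = d[0]; Y = d[1]; Z = d[2]; C = d[3]; N = d[4];
}

// Fill the patch matrix for one (offset, ci) column across all samples.
static void im2col_fill(arma::mat& A, const double* xp,
                        int X, int Y, int Z, int Ci, int N, int K) {
  int p = (K - 1) / 2;
  R_xlen_t sv = (R_xlen_t)X * Y * Z;
  for (int ci = 0; ci < Ci; ci++) {
    for (int dz = 0; dz < K; dz++)
    for (int dy = 0; dy < K; dy++)
    for (int dx = 0; dx < K; dx++) {
      int col = (dx + K * (dy + K * dz)) + K * K * K * ci;
      double* ac = A.colptr(col);
      int oz = dz - p, oy = dy - p, ox = dx - p;
      for (int n = 0; n < N; n++) {
        const double* xs = xp + sv * (ci + (R_xlen_t)Ci * n);
        double* an = ac + sv * n;
        for (int k = 0; k < Z; k++) {
          int iz = k + oz;
          if (iz < 0 || iz >= Z) {
            for (R_xlen_t t = (R_xlen_t)k * X * Y; t < (R_xlen_t)(k + 1) * X * Y; t++) an[t] = 0.0;
            continue;
          }
          for (int j = 0; j < Y; j++) {
            int iy = j + oy;
            double* arow = an + (R_xlen_t)k * X * Y + (R_xlen_t)j * X;
            if (iy < 0 || iy >= Y) {
              for (int i = 0; i < X; i++) arow[i] = 0.0;
              continue;
            }
            const double* xrow = xs + (R_xlen_t)iz * X * Y + (R_xlen_t)iy * X;
            int ilo = ox < 0 ? -ox : 0, ihi = ox > 0 ? X - ox : X;
            for (int i = 0; i < ilo; i++) arow[i] = 0.0;
            for (int i = ilo; i < ihi; i++) arow[i] = xrow[i + ox];
            for (int i = ihi; i < X; i++) arow[i] = 0.0;
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv3d_fw(NumericVector x, NumericVector w, NumericVector b) {
  int X, Y, Z, Ci, N;
  dims5c(x, X, Y, Z, Ci, N);
  IntegerVector wd = w.attr("dim");
  int K = wd[0], Co = wd[4];
  if (wd[3] != Ci) stop("weight input channels do not match input");
  R_xlen_t sv = (R_xlen_t)X * Y * Z;

  arma::mat A((R_xlen_t)sv * N, (R_xlen_t)K * K * K * Ci);
  im2col_fill(A, REAL(x), X, Y, Z, Ci, N, K);
  arma::mat W(REAL(w), (R_xlen_t)K * K * K * Ci, Co, false, true);
  arma::mat Ym = A * W;  // (V*N) x Co

  NumericVector y(sv * Co * N);
  y.attr("dim") = IntegerVector::create(X, Y, Z, Co, N);
  double* yp = REAL(y);
  const double* bp = REAL(b);
  for (int n = 0; n < N; n++)
  for (int co = 0; co < Co; co++) {
    const double* src = Ym.colptr(co) + sv * n;
    double* dst = yp + sv * (co + (R_xlen_t)Co * n);
    double bv = bp[co];
    for (R_xlen_t t = 0; t < sv; t++) dst[t] = src[t] + bv;
  }
  return y;
}

// [[Rcpp::export]]
List conv3d_bw(NumericVector x, NumericVector w, NumericVector gy) {
  int X, Y, Z, Ci, N;
  dims5c(x, X, Y, Z, Ci, N);
  IntegerVector wd = w.attr("dim");
  int K = wd[0], Co = wd[4];
  int p = (K - 1) / 2;
  R_xlen_t sv = (R_xlen_t)X * Y * Z;

  // gy as (V*N) x Co
  arma::mat Gy((R_xlen_t)sv * N, Co);
  const double* gyp = REAL(gy);
  for (int n = 0; n < N; n++)
  for (int co = 0; co < Co; co++) {
    const double* src = gyp + sv * (co + (R_xlen_t)Co * n);
    double* dst = Gy.colptr(co) + sv * n;
    for (R_xlen_t t = 0; t < sv; t++) dst[t] = src[t];
  }

  arma::mat A((R_xlen_t)sv * N, (R_xlen_t)K * K * K * Ci);
  im2col_fill(A, REAL(x), X, Y, Z, Ci, N, K);

  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  {
    arma::mat GW(REAL(gw), (R_xlen_t)K * K * K * Ci, Co, false, true);
    GW = A.t() * Gy;
  }

  NumericVector gb(Co);
  for (int co = 0; co < Co; co++) gb[co] = arma::accu(Gy.col(co));

  arma::mat W(REAL(w), (R_xlen_t)K * K * K * Ci, Co, false, true);
  arma::mat GA = Gy * W.t();  // (V*N) x (K^3*Ci)

  // col2im scatter-add back onto input positions
  NumericVector gx(x.size());
  gx.attr("dim") = x.attr("dim");
  double* gxp = REAL(gx);
  for (int ci = 0; ci < Ci; ci++) {
    for (int dz = 0; dz < K; dz++)
    for (int dy = 0; dy < K; dy++)
    for (int dx = 0; dx < K; dx++) {
      int col = (dx + K * (dy + K * dz)) + K * K * K * ci;
      const double* gc = GA.colptr(col);
      int oz = dz - p, oy = dy - p, ox = dx - p;
      for (int n = 0; n < N; n++) {
        double* gs = gxp + sv * (ci + (R_xlen_t)Ci * n);
        const double* gn = gc + sv * n;
        int klo = oz < 0 ? -oz : 0, khi = oz > 0 ? Z - oz : Z;
        int jlo = oy < 0 ? -oy : 0, jhi = oy > 0 ? Y - oy : Y;
        int ilo = ox < 0 ? -ox : 0, ihi = ox > 0 ? X - ox : X;
        for (int k = klo; k < khi; k++) {
          for (int j = jlo; j < jhi; j++) {
            double* grow = gs + (R_xlen_t)(k + oz) * X * Y + (R_xlen_t)(j + oy) * X + (ilo + ox);
            const double* gyrow = gn + (R_xlen_t)k * X * Y + (R_xlen_t)j * X + ilo;
            int len = ihi - ilo;
            for (int i = 0; i < len; i++) grow[i] += gyrow[i];
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
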
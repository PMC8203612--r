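#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
# define FCONE
#endif
using namespace Rcpp;

// Fused convolution forward/backward: im2col + BLAS dgemm + layout
// transpose in one C++ pass, avoiding R-side aperm copies. Tensor layout is
// (H, W, C, N) column-major; weights are (Cout x kh*kw*Cin) with kernel rows
// ordered (dy, dx, c), dy fastest. Images are processed in chunks large
// enough to make the GEMMs efficient while bounding the im2col buffer.

static void im2col_one(const double* xn, int H, int W, int C,
                       int k, int stride, int pad,
                       int Ho, int Wo, double* cols) {
  const int rows = k * k * C;
  for (int wo = 0; wo < Wo; ++wo) {
    for (int ho = 0; ho < Ho; ++ho) {
      double* oc = cols + (R_xlen_t)(ho + Ho * wo) * rows;
      for (int c = 0; c < C; ++c) {
        const double* xc = xn + (R_xlen_t)H * W * c;
        for (int dx = 0; dx < k; ++dx) {
          const int wi = wo * stride - pad + dx;
          const bool win = wi >= 0 && wi < W;
          for (int dy = 0; dy < k; ++dy) {
            const int hi = ho * stride - pad + dy;
            oc[dy + k * (dx + k * c)] =
              (win && hi >= 0 && hi < H) ? xc[hi + (R_xlen_t)H * wi] : 0.0;
          }
        }
      }
    }
  }
}

static int chunk_images(int R, int M, int N) {
  const R_xlen_t budget = 8000000; // doubles (~64 MB) for the cols buffer
  R_xlen_t per = (R_xlen_t)R * M;
  int chunk = per > 0 ? (int)std::max((R_xlen_t)1, budget / per) : N;
  return std::min(chunk, N);
}

// [[Rcpp::export]]
NumericVector cpp_conv_fw(NumericVector x, NumericMatrix Wm, NumericVector b,
                          int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Cout = Wm.nrow();
  const int R = Wm.ncol();
  const int M = Ho * Wo;
  const int chunk = chunk_images(R, M, N);
  NumericVector out((R_xlen_t)M * Cout * N);
  std::vector<double> cols((R_xlen_t)R * M * chunk);
  std::vector<double> y((R_xlen_t)Cout * M * chunk);
  const double one = 1.0, zero = 0.0;
  const double* xp = REAL(x);
  const double* wp = REAL(Wm);
  double* op = REAL(out);
  for (int n0 = 0; n0 < N; n0 += chunk) {
    const int nc = std::min(chunk, N - n0);
    for (int j = 0; j < nc; ++j) {
      im2col_one(xp + (R_xlen_t)H * W * C * (n0 + j), H, W, C, k, stride,
                 pad, Ho, Wo, cols.data() + (R_xlen_t)R * M * j);
    }
    const int Mc = M * nc;
    F77_CALL(dgemm)("N", "N", &Cout, &Mc, &R, &one, wp, &Cout,
                    cols.data(), &R, &zero, y.data(), &Cout FCONE FCONE);
    // y is (Cout x M*nc); transpose into (M, Cout) per image, adding bias
    for (int j = 0; j < nc; ++j) {
      double* on = op + (R_xlen_t)M * Cout * (n0 + j);
      const double* yj = y.data() + (R_xlen_t)Cout * M * j;
      for (int c = 0; c < Cout; ++c) {
        const double bc = b[c];
        double* oc = on + (R_xlen_t)M * c;
        const double* yc = yj + c;
        for (int p = 0; p < M; ++p) oc[p] = yc[(R_xlen_t)Cout * p] + bc;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bw(NumericVector x, NumericMatrix Wm, NumericVector dy,
                 int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], N = d[3];
  const int Ho = (H + 2 * pad - k) / stride + 1;
  const int Wo = (W + 2 * pad - k) / stride + 1;
  const int Cout = Wm.nrow();
  const int R = Wm.ncol();
  const int M = Ho * Wo;
  const int chunk = chunk_images(R, M, N);
  NumericMatrix dW(Cout, R);
  NumericVector db(Cout);
  NumericVector dx((R_xlen_t)H * W * C * N);
  std::vector<double> cols((R_xlen_t)R * M * chunk);
  std::vector<double> dymat((R_xlen_t)Cout * M * chunk);
  std::vector<double> dcols((R_xlen_t)R * M * chunk);
  const double one = 1.0, zero = 0.0;
  const double* xp = REAL(x);
  const double* wp = REAL(Wm);
  const double* dyp = REAL(dy);
  double* dwp = REAL(dW);
  double* dbp = REAL(db);
  double* dxp = REAL(dx);
  for (int n0 = 0; n0 < N; n0 += chunk) {
    const int nc = std::min(chunk, N - n0);
    for (int j = 0; j < nc; ++j) {
      const double* dyn = dyp + (R_xlen_t)M * Cout * (n0 + j);
      double* tj = dymat.data() + (R_xlen_t)Cout * M * j;
      for (int c = 0; c < Cout; ++c) {
        const double* dc = dyn + (R_xlen_t)M * c;
        double* tm = tj + c;
        double acc = 0.0;
        for (int p = 0; p < M; ++p) {
          tm[(R_xlen_t)Cout * p] = dc[p];
          acc += dc[p];
        }
        dbp[c] += acc;
      }
      im2col_one(xp + (R_xlen_t)H * W * C * (n0 + j), H, W, C, k, stride,
                 pad, Ho, Wo, cols.data() + (R_xlen_t)R * M * j);
    }
    const int Mc = M * nc;
    // dW += dymat (Cout x Mc) * cols^T (Mc x R)
    F77_CALL(dgemm)("N", "T", &Cout, &R, &Mc, &one, dymat.data(), &Cout,
                    cols.data(), &R, &one, dwp, &Cout FCONE FCONE);
    // dcols (R x Mc) = Wm^T * dymat
    F77_CALL(dgemm)("T", "N", &R, &Mc, &Cout, &one, wp, &Cout,
                    dymat.data(), &Cout, &zero, dcols.data(), &R FCONE FCONE);
    for (int j = 0; j < nc; ++j) {
      // col2im scatter-add into dx image n0 + j
      double* dxn = dxp + (R_xlen_t)H * W * C * (n0 + j);
      const double* dcj = dcols.data() + (R_xlen_t)R * M * j;
      for (int wo = 0; wo < Wo; ++wo) {
        for (int ho = 0; ho < Ho; ++ho) {
          const double* cc = dcj + (R_xlen_t)(ho + Ho * wo) * R;
          for (int c = 0; c < C; ++c) {
            double* oc = dxn + (R_xlen_t)H * W * c;
            for (int dxk = 0; dxk < k; ++dxk) {
              const int wi = wo * stride - pad + dxk;
              if (wi < 0 || wi >= W) continue;
              for (int dyk = 0; dyk < k; ++dyk) {
                const int hi = ho * stride - pad + dyk;
                if (hi < 0 || hi >= H) continue;
                oc[hi + (R_xlen_t)H * wi] += cc[dyk + k * (dxk + k * c)];
              }
            }
          }
        }
      }
    }
  }
  dx.attr("dim") = d;
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}
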
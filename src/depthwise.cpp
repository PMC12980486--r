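#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Tensors use channel-first (C, B, T) layout: a length-C vector broadcasts
// along the fastest axis and time slices are contiguous planes of C * B.

// Depthwise 1D convolution along T (valid): one kernel per channel.
// Z: (C, B, T), w: (L, C), b: C. Returns Y: (C, B, Tout), Tout = T - L + 1.
// [[Rcpp::export(name = ".dw_conv_forward")]]
NumericVector dw_conv_forward(NumericVector Z, NumericMatrix w, NumericVector b,
                              int C, int B, int T) {
  const int L = w.nrow();
  const int Tout = T - L + 1;
  NumericVector Y(static_cast<R_xlen_t>(C) * B * Tout);
  const double *z = Z.begin();
  double *y = Y.begin();
  const R_xlen_t plane = static_cast<R_xlen_t>(C) * B;
  // contiguous per-lag weight rows so the inner loop vectorizes
  std::vector<double> wr(static_cast<size_t>(L) * C);
  for (int l = 0; l < L; ++l)
    for (int c = 0; c < C; ++c) wr[static_cast<size_t>(l) * C + c] = w(l, c);
  for (int t = 0; t < Tout; ++t) {
    double *yt = y + plane * t;
    for (int bb = 0; bb < B; ++bb) {
      double *yc = yt + static_cast<R_xlen_t>(bb) * C;
      for (int c = 0; c < C; ++c) yc[c] = b[c];
    }
    for (int l = 0; l < L; ++l) {
      const double *zt = z + plane * (t + l);
      const double *wl = wr.data() + static_cast<size_t>(l) * C;
      for (int bb = 0; bb < B; ++bb) {
        const double *zc = zt + static_cast<R_xlen_t>(bb) * C;
        double *yc = yt + static_cast<R_xlen_t>(bb) * C;
        for (int c = 0; c < C; ++c) yc[c] += zc[c] * wl[c];
      }
    }
  }
  return Y;
}

// Backward of the depthwise convolution.
// dY: (C, B, Tout); Z: (C, B, T); w: (L, C).
// Returns list(dZ (C,B,T), dw (L,C), db (C)).
// [[Rcpp::export(name = ".dw_conv_backward")]]
List dw_conv_backward(NumericVector dY, NumericVector Z, NumericMatrix w,
                      int C, int B, int T) {
  const int L = w.nrow();
  const int Tout = T - L + 1;
  const R_xlen_t plane = static_cast<R_xlen_t>(C) * B;
  NumericVector dZ(static_cast<R_xlen_t>(C) * B * T);
  NumericMatrix dw(L, C);
  NumericVector db(C);
  const double *dy = dY.begin();
  const double *z = Z.begin();
  double *dz = dZ.begin();
  std::vector<double> wr(static_cast<size_t>(L) * C);
  std::vector<double> dwr(static_cast<size_t>(L) * C, 0.0);
  for (int l = 0; l < L; ++l)
    for (int c = 0; c < C; ++c) wr[static_cast<size_t>(l) * C + c] = w(l, c);
  for (int t = 0; t < Tout; ++t) {
    const double *dyt = dy + plane * t;
    for (int bb = 0; bb < B; ++bb) {
      const double *dyc = dyt + static_cast<R_xlen_t>(bb) * C;
      for (int c = 0; c < C; ++c) db[c] += dyc[c];
    }
    for (int l = 0; l < L; ++l) {
      const double *zt = z + plane * (t + l);
      double *dzt = dz + plane * (t + l);
      const double *wl = wr.data() + static_cast<size_t>(l) * C;
      double *dwl = dwr.data() + static_cast<size_t>(l) * C;
      for (int bb = 0; bb < B; ++bb) {
        const R_xlen_t off = static_cast<R_xlen_t>(bb) * C;
        const double *zc = zt + off;
        const double *dyc = dyt + off;
        double *dzc = dzt + off;
        for (int c = 0; c < C; ++c) {
          dwl[c] += dyc[c] * zc[c];
          dzc[c] += dyc[c] * wl[c];
        }
      }
    }
  }
  for (int l = 0; l < L; ++l)
    for (int c = 0; c < C; ++c) dw(l, c) = dwr[static_cast<size_t>(l) * C + c];
  return List::create(_["dZ"] = dZ, _["dw"] = dw, _["db"] = db);
}

// Non-overlapping max pool along T with window P (remainder dropped).
// Y: (C, B, Tout). Returns list(M (C,B,J), argmax (C,B,J) in 1..P).
// [[Rcpp::export(name = ".dw_maxpool_forward")]]
List dw_maxpool_forward(NumericVector Y, int C, int B, int Tout, int P) {
  const int J = Tout / P;
  const R_xlen_t plane = static_cast<R_xlen_t>(C) * B;
  NumericVector M(plane * J);
  IntegerVector A(plane * J);
  const double *y = Y.begin();
  double *m = M.begin();
  int *a = A.begin();
  for (int j = 0; j < J; ++j) {
    double *mj = m + plane * j;
    int *aj = a + plane * j;
    const double *y0 = y + plane * (static_cast<R_xlen_t>(j) * P);
    for (R_xlen_t i = 0; i < plane; ++i) { mj[i] = y0[i]; aj[i] = 1; }
    for (int p = 1; p < P; ++p) {
      const double *yp = y + plane * (static_cast<R_xlen_t>(j) * P + p);
      for (R_xlen_t i = 0; i < plane; ++i) {
        if (yp[i] > mj[i]) { mj[i] = yp[i]; aj[i] = p + 1; }
      }
    }
  }
  return List::create(_["M"] = M, _["argmax"] = A);
}

// Route pooled gradients back to the argmax positions.
// [[Rcpp::export(name = ".dw_maxpool_backward")]]
NumericVector dw_maxpool_backward(NumericVector dM, IntegerVector A,
                                  int C, int B, int Tout, int P) {
  const int J = Tout / P;
  const R_xlen_t plane = static_cast<R_xlen_t>(C) * B;
  NumericVector dY(plane * Tout);
  const double *dm = dM.begin();
  const int *a = A.begin();
  double *dy = dY.begin();
  for (int j = 0; j < J; ++j) {
    const double *dmj = dm + plane * j;
    const int *aj = a + plane * j;
    for (R_xlen_t i = 0; i < plane; ++i) {
      dy[plane * (static_cast<R_xlen_t>(j) * P + (aj[i] - 1)) + i] = dmj[i];
    }
  }
  return dY;
}
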
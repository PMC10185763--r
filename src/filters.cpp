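#include <Rcpp.h>
using namespace Rcpp;

// Zero-phase IIR filtering as cascaded second-order sections (biquads,
// direct form II transposed), applied forward then backward along each
// column of X. sos is nsec x 6: b0 b1 b2 a0 a1 a2 per section (a0 == 1).
// Narrow low-frequency Butterworth designs are numerically unstable in
// expanded transfer-function form; the biquad cascade is the standard
// stable realisation. Initial state zero: callers pad the signal so edge
// transients fall outside the retained samples.
// [[Rcpp::export]]
NumericMatrix cpp_sosfiltfilt(NumericMatrix sos, NumericMatrix X) {
  const int nsec = sos.nrow();
  const int T = X.nrow(), M = X.ncol();
  NumericMatrix Y(T, M);
  std::vector<double> buf(T);
  for (int m = 0; m < M; ++m) {
    for (int t = 0; t < T; ++t) buf[t] = X(t, m);
    for (int pass = 0; pass < 2; ++pass) {
      for (int s = 0; s < nsec; ++s) {
        const double b0 = sos(s, 0), b1 = sos(s, 1), b2 = sos(s, 2);
        const double a1 = sos(s, 4), a2 = sos(s, 5);
        double z1 = 0.0, z2 = 0.0;
        for (int t = 0; t < T; ++t) {
          const double x = buf[t];
          const double y = b0 * x + z1;
          z1 = b1 * x + z2 - a1 * y;
          z2 = b2 * x - a2 * y;
          buf[t] = y;
        }
      }
      std::reverse(buf.begin(), buf.end());
    }
    for (int t = 0; t < T; ++t) Y(t, m) = buf[t];
  }
  return Y;
}

// Same-length 1-D convolution of every column of X (T x M) with each of the
// F kernels in W (K x F): y(t, m, f) = sum_k W(k, f) * X(t + k - off, m),
// zero outside [0, T). Returns a T x M x F array.
// [[Rcpp::export]]
NumericVector cpp_conv_same(NumericMatrix X, NumericMatrix W, int off) {
  const int T = X.nrow(), M = X.ncol(), K = W.nrow(), F = W.ncol();
  NumericVector out(static_cast<R_xlen_t>(T) * M * F);
  for (int f = 0; f < F; ++f) {
    const double *w = &W(0, f);
    for (int m = 0; m < M; ++m) {
      const double *x = &X(0, m);
      double *y = &out[(static_cast<R_xlen_t>(f) * M + m) * T];
      for (int t = 0; t < T; ++t) {
        const int k0 = std::max(0, off - t);
        const int k1 = std::min(K - 1, T - 1 - t + off);
        double acc = 0.0;
        const double *xs = x + t - off;
        for (int k = k0; k <= k1; ++k) acc += w[k] * xs[k];
        y[t] = acc;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(T, M, F);
  return out;
}

// Gradient of cpp_conv_same with respect to W.
// G is the T x M x F gradient at the output; returns K x F.
// [[Rcpp::export]]
NumericMatrix cpp_conv_gradw(NumericMatrix X, NumericVector G, int K, int off) {
  const int T = X.nrow(), M = X.ncol();
  IntegerVector dims = G.attr("dim");
  const int F = dims[2];
  NumericMatrix gw(K, F);
  for (int f = 0; f < F; ++f) {
    for (int m = 0; m < M; ++m) {
      const double *x = &X(0, m);
      const double *g = &G[(static_cast<R_xlen_t>(f) * M + m) * T];
      for (int k = 0; k < K; ++k) {
        const int t0 = std::max(0, off - k);
        const int t1 = std::min(T - 1, T - 1 - k + off);
        double acc = 0.0;
        const double *xs = x + k - off;
        for (int t = t0; t <= t1; ++t) acc += xs[t] * g[t];
        gw(k, f) += acc;
      }
    }
  }
  return gw;
}
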
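#include <Rcpp.h>
using namespace Rcpp;

// causal direct-form-I IIR pass over a contiguous buffer
static void iir_pass(const std::vector<double>& x, std::vector<double>& y,
                     const NumericVector& b, const NumericVector& a) {
  const int n = x.size(), nb = b.size(), na = a.size();
  for (int t = 0; t < n; ++t) {
    double acc = b[0] * x[t];
    for (int k = 1; k < nb && k <= t; ++k) acc += b[k] * x[t - k];
    for (int k = 1; k < na && k <= t; ++k) acc -= a[k] * y[t - k];
    y[t] = acc / a[0];
  }
}

// Zero-phase forward-backward IIR filtering of every column of X
// (columns are time series), with odd-reflection padding of `padlen`
// samples at each end.
// [[Rcpp::export(name = ".filtfilt_cols")]]
NumericMatrix filtfilt_cols(NumericMatrix X, NumericVector b, NumericVector a,
                            int padlen) {
  const int n = X.nrow(), nc = X.ncol();
  if (padlen >= n) stop("padlen must be smaller than the series length");
  const int ne = n + 2 * padlen;
  NumericMatrix out(n, nc);
  std::vector<double> e(ne), y(ne);
  for (int j = 0; j < nc; ++j) {
    const double* col = &X(0, j);
    for (int i = 0; i < padlen; ++i)
      e[i] = 2.0 * col[0] - col[padlen - i];
    for (int i = 0; i < n; ++i) e[padlen + i] = col[i];
    for (int i = 0; i < padlen; ++i)
      e[padlen + n + i] = 2.0 * col[n - 1] - col[n - 2 - i];
    iir_pass(e, y, b, a);
    std::reverse(y.begin(), y.end());
    iir_pass(y, e, b, a);          // reuse e as the output buffer
    std::reverse(e.begin(), e.end());
    for (int i = 0; i < n; ++i) out(i, j) = e[padlen + i];
  }
  return out;
}

// Separable 1-D convolution along the first dimension of a matrix whose
// rows are the filtered axis: out = K %*% M with K banded (kernel w,
// half-width h) and rows renormalised at the borders.
// [[Rcpp::export(name = ".conv_axis")]]
NumericMatrix conv_axis(NumericMatrix M, NumericVector w, int h) {
  const int n = M.nrow(), nc = M.ncol();
  NumericMatrix out(n, nc);
  std::vector<double> norm(n);
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int k = -h; k <= h; ++k) {
      int j = i + k;
      if (j >= 0 && j < n) s += w[k + h];
    }
    norm[i] = s;
  }
  for (int c = 0; c < nc; ++c) {
    const double* col = &M(0, c);
    double* oc = &out(0, c);
    for (int i = 0; i < n; ++i) {
      double acc = 0.0;
      for (int k = -h; k <= h; ++k) {
        int j = i + k;
        if (j >= 0 && j < n) acc += w[k + h] * col[j];
      }
      oc[i] = acc / norm[i];
    }
  }
  return out;
}
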
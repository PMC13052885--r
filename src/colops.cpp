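#include <Rcpp.h>
using namespace Rcpp;

// column-broadcast kernels: out[i,j] combines X[i,j] with v[j] in one pass

// [[Rcpp::export(name = ".add_col_cpp")]]
NumericMatrix add_col_cpp(NumericMatrix X, NumericVector v) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    const double vj = v[j];
    const double *src = &X(0, j);
    double *dst = &out(0, j);
    for (int i = 0; i < n; ++i) dst[i] = src[i] + vj;
  }
  return out;
}

// [[Rcpp::export(name = ".mul_col_cpp")]]
NumericMatrix mul_col_cpp(NumericMatrix X, NumericVector v) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    const double vj = v[j];
    const double *src = &X(0, j);
    double *dst = &out(0, j);
    for (int i = 0; i < n; ++i) dst[i] = src[i] * vj;
  }
  return out;
}

// (X[i,j] - mu[j]) * sd[j]
// [[Rcpp::export(name = ".scale_shift_cpp")]]
NumericMatrix scale_shift_cpp(NumericMatrix X, NumericVector mu,
                              NumericVector sd) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    const double mj = mu[j], sj = sd[j];
    const double *src = &X(0, j);
    double *dst = &out(0, j);
    for (int i = 0; i < n; ++i) dst[i] = (src[i] - mj) * sj;
  }
  return out;
}

// X[i,j] * g[j] + b[j]
// [[Rcpp::export(name = ".muladd_col_cpp")]]
NumericMatrix muladd_col_cpp(NumericMatrix X, NumericVector g,
                             NumericVector b) {
  const int n = X.nrow(), m = X.ncol();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    const double gj = g[j], bj = b[j];
    const double *src = &X(0, j);
    double *dst = &out(0, j);
    for (int i = 0; i < n; ++i) dst[i] = src[i] * gj + bj;
  }
  return out;
}
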
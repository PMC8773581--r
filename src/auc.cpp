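#include <Rcpp.h>
using namespace Rcpp;

// Mann-Whitney AUC by pair counting: P(y > x) + 0.5 P(y == x).
static double auc_pair(const double* x, int nx, const double* y, int ny) {
  double s = 0.0;
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      if (y[j] > x[i]) s += 1.0;
      else if (y[j] == x[i]) s += 0.5;
    }
  }
  return s / ((double)nx * (double)ny);
}

// [[Rcpp::export]]
double cpp_auc(NumericVector x, NumericVector y) {
  return auc_pair(x.begin(), x.size(), y.begin(), y.size());
}

// Column-wise AUC for two subject-by-feature matrices.
// [[Rcpp::export]]
NumericVector cpp_auc_matrix(NumericMatrix X, NumericMatrix Y) {
  int p = X.ncol();
  NumericVector out(p);
  for (int c = 0; c < p; ++c) {
    out[c] = auc_pair(&X(0, c), X.nrow(), &Y(0, c), Y.nrow());
  }
  return out;
}

// Bootstrap AUC over columns: IX (B x nx) and IY (B x ny) hold 0-based
// subject resample indices; returns a B x p matrix of AUC values.
// [[Rcpp::export]]
NumericMatrix cpp_auc_boot(NumericMatrix X, NumericMatrix Y,
                           IntegerMatrix IX, IntegerMatrix IY) {
  int nx = X.nrow(), ny = Y.nrow(), p = X.ncol(), B = IX.nrow();
  NumericMatrix out(B, p);
  std::vector<double> xb(nx), yb(ny);
  for (int c = 0; c < p; ++c) {
    for (int b = 0; b < B; ++b) {
      for (int i = 0; i < nx; ++i) xb[i] = X(IX(b, i), c);
      for (int j = 0; j < ny; ++j) yb[j] = Y(IY(b, j), c);
      out(b, c) = auc_pair(xb.data(), nx, yb.data(), ny);
    }
  }
  return out;
}
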
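#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Direct-form II transposed IIR filter with explicit initial state.
// zi has length max(len(a), len(b)) - 1; pass zeros for a cold start.
// [[Rcpp::export]]
NumericVector iir_filter_cpp(NumericVector b, NumericVector a,
                             NumericVector x, NumericVector zi) {
  int nf = std::max(b.size(), a.size());
  std::vector<double> bb(nf, 0.0), aa(nf, 0.0);
  for (int i = 0; i < b.size(); ++i) bb[i] = b[i];
  for (int i = 0; i < a.size(); ++i) aa[i] = a[i];
  double a0 = aa[0];
  if (a0 == 0.0) stop("a[1] must be non-zero");
  for (int i = 0; i < nf; ++i) { bb[i] /= a0; aa[i] /= a0; }

  std::vector<double> z(nf - 1, 0.0);
  for (int i = 0; i < zi.size() && i < nf - 1; ++i) z[i] = zi[i];

  int n = x.size();
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = bb[0] * xi + (nf > 1 ? z[0] : 0.0);
    for (int k = 0; k + 1 < nf - 1; ++k)
      z[k] = bb[k + 1] * xi + z[k + 1] - aa[k + 1] * yi;
    if (nf > 1) z[nf - 2] = bb[nf - 1] * xi - aa[nf - 1] * yi;
    y[i] = yi;
  }
  return y;
}

// Centered moving average with shrinking windows at the edges.
// [[Rcpp::export]]
NumericVector moving_average_cpp(NumericVector x, int k) {
  int n = x.size();
  if (k < 1) stop("window must be >= 1");
  int half = k / 2;
  std::vector<double> cs(n + 1, 0.0);
  for (int i = 0; i < n; ++i) cs[i + 1] = cs[i] + x[i];
  NumericVector y(n);
  for (int i = 0; i < n; ++i) {
    int lo = std::max(0, i - half);
    int hi = std::min(n - 1, i + half);
    y[i] = (cs[hi + 1] - cs[lo]) / (hi - lo + 1);
  }
  return y;
}
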
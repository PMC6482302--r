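#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Soft-margin binary SVM (RBF kernel) trained by SMO with maximal-
// violating-pair working-set selection and per-sample box constraints
// (class weighting). Fully deterministic: ties resolve to the lowest
// index, no RNG anywhere.

static inline double rbf(const NumericMatrix& X, int i, int j, double gamma) {
  double s = 0.0;
  int d = X.ncol();
  for (int k = 0; k < d; ++k) {
    double diff = X(i, k) - X(j, k);
    s += diff * diff;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export]]
List smo_train_cpp(NumericMatrix X, NumericVector y, NumericVector C,
                   double gamma, double tol, int max_iter) {
  int n = X.nrow();
  std::vector<std::vector<double> > K(n, std::vector<double>(n));
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      K[i][j] = K[j][i] = rbf(X, i, j, gamma);

  std::vector<double> alpha(n, 0.0), f(n, 0.0); // f_i = sum_j a_j y_j K_ij
  const double eps = 1e-12;
  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // working pair: i = argmax_{I_up} (-E_t), j = argmin_{I_low} (-E_t),
    // where E_t = f_t - y_t; I_up / I_low are the feasible move sets
    int i = -1, j = -1;
    double up = -HUGE_VAL, lo = HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      double v = y[t] - f[t]; // -E_t
      bool in_up = (y[t] > 0 && alpha[t] < C[t] - eps) ||
                   (y[t] < 0 && alpha[t] > eps);
      bool in_lo = (y[t] > 0 && alpha[t] > eps) ||
                   (y[t] < 0 && alpha[t] < C[t] - eps);
      if (in_up && v > up) { up = v; i = t; }
      if (in_lo && v < lo) { lo = v; j = t; }
    }
    if (i < 0 || j < 0 || up - lo < tol) break;

    double Ei = f[i] - y[i], Ej = f[j] - y[j];
    double ai = alpha[i], aj = alpha[j], L, H;
    if (y[i] != y[j]) {
      L = std::max(0.0, aj - ai);
      H = std::min(C[j], C[i] + aj - ai);
    } else {
      L = std::max(0.0, ai + aj - C[i]);
      H = std::min(C[j], ai + aj);
    }
    if (H - L < eps) break;
    double eta = 2.0 * K[i][j] - K[i][i] - K[j][j];
    if (eta > -eps) eta = -eps;
    double aj_new = aj - y[j] * (Ei - Ej) / eta;
    if (aj_new > H) aj_new = H;
    if (aj_new < L) aj_new = L;
    if (std::fabs(aj_new - aj) < eps) break;
    double ai_new = ai + y[i] * y[j] * (aj - aj_new);
    double di = y[i] * (ai_new - ai), dj = y[j] * (aj_new - aj);
    for (int k = 0; k < n; ++k) f[k] += di * K[i][k] + dj * K[j][k];
    alpha[i] = ai_new;
    alpha[j] = aj_new;
  }

  // intercept from the free support vectors (midpoint of the violating
  // bounds if none are free)
  double bsum = 0.0;
  int bcnt = 0;
  double up = -HUGE_VAL, lo = HUGE_VAL;
  for (int t = 0; t < n; ++t) {
    double v = y[t] - f[t];
    if (alpha[t] > eps && alpha[t] < C[t] - eps) { bsum += v; ++bcnt; }
    bool in_up = (y[t] > 0 && alpha[t] < C[t] - eps) ||
                 (y[t] < 0 && alpha[t] > eps);
    bool in_lo = (y[t] > 0 && alpha[t] > eps) ||
                 (y[t] < 0 && alpha[t] < C[t] - eps);
    if (in_up && v > up) up = v;
    if (in_lo && v < lo) lo = v;
  }
  double b = bcnt > 0 ? bsum / bcnt
                      : (std::isfinite(up) && std::isfinite(lo) ? 0.5 * (up + lo)
                                                                : 0.0);

  NumericVector alpha_out(n);
  for (int t = 0; t < n; ++t) alpha_out[t] = alpha[t];
  return List::create(_["alpha"] = alpha_out, _["b"] = b,
                      _["iterations"] = iter);
}

// Decision values sum_i coef_i * K(sv_i, x) + b for rows of Xnew.
// [[Rcpp::export]]
NumericVector smo_decision_cpp(NumericMatrix Xsv, NumericVector coef, double b,
                               double gamma, NumericMatrix Xnew) {
  int ns = Xsv.nrow(), m = Xnew.nrow(), d = Xsv.ncol();
  NumericVector out(m);
  for (int r = 0; r < m; ++r) {
    double acc = b;
    for (int i = 0; i < ns; ++i) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = Xsv(i, k) - Xnew(r, k);
        s += diff * diff;
      }
      acc += coef[i] * std::exp(-gamma * s);
    }
    out[r] = acc;
  }
  return out;
}
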
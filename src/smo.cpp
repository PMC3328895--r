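#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Binary soft-margin SVM with RBF kernel, trained by a simplified SMO
// (Platt-style working-set of one pair per iteration). Sized for the
// small problems this package meets (n of order 100).

static inline double rbf(const NumericMatrix& X, int i, int j, double gamma) {
  double s = 0.0;
  int p = X.ncol();
  for (int k = 0; k < p; ++k) {
    double d = X(i, k) - X(j, k);
    s += d * d;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export]]
List smo_train(NumericMatrix X, NumericVector y, double C, double gamma,
               double tol = 1e-3, int max_passes = 10, int max_iter = 20000) {
  int n = X.nrow();
  std::vector<double> alpha(n, 0.0);
  double b = 0.0;

  // cache the kernel matrix (n is small)
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i)
    for (int j = i; j < n; ++j)
      K(i, j) = K(j, i) = rbf(X, i, j, gamma);

  auto f = [&](int i) {
    double s = b;
    for (int k = 0; k < n; ++k)
      if (alpha[k] > 0.0) s += alpha[k] * y[k] * K(k, i);
    return s;
  };

  int passes = 0, iter = 0;
  GetRNGstate();
  while (passes < max_passes && iter < max_iter) {
    int changed = 0;
    for (int i = 0; i < n; ++i) {
      ++iter;
      double Ei = f(i) - y[i];
      if ((y[i] * Ei < -tol && alpha[i] < C) ||
          (y[i] * Ei > tol && alpha[i] > 0)) {
        int j = (int)(unif_rand() * (n - 1));
        if (j >= i) ++j;
        double Ej = f(j) - y[j];
        double ai_old = alpha[i], aj_old = alpha[j];
        double L, H;
        if (y[i] != y[j]) {
          L = std::max(0.0, aj_old - ai_old);
          H = std::min(C, C + aj_old - ai_old);
        } else {
          L = std::max(0.0, ai_old + aj_old - C);
          H = std::min(C, ai_old + aj_old);
        }
        if (L >= H) continue;
        double eta = 2.0 * K(i, j) - K(i, i) - K(j, j);
        if (eta >= 0) continue;
        double aj = aj_old - y[j] * (Ei - Ej) / eta;
        aj = std::min(H, std::max(L, aj));
        if (std::fabs(aj - aj_old) < 1e-7) continue;
        double ai = ai_old + y[i] * y[j] * (aj_old - aj);
        alpha[i] = ai;
        alpha[j] = aj;
        double b1 = b - Ei - y[i] * (ai - ai_old) * K(i, i) -
                    y[j] * (aj - aj_old) * K(i, j);
        double b2 = b - Ej - y[i] * (ai - ai_old) * K(i, j) -
                    y[j] * (aj - aj_old) * K(j, j);
        if (ai > 0 && ai < C) b = b1;
        else if (aj > 0 && aj < C) b = b2;
        else b = 0.5 * (b1 + b2);
        ++changed;
      }
    }
    if (changed == 0) ++passes; else passes = 0;
  }
  PutRNGstate();

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b);
}

// [[Rcpp::export]]
NumericVector smo_decision(NumericMatrix Xtrain, NumericVector y,
                           NumericVector alpha, double b, double gamma,
                           NumericMatrix Xnew) {
  int n = Xtrain.nrow(), m = Xnew.nrow(), p = Xtrain.ncol();
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double s = b;
    for (int i = 0; i < n; ++i) {
      if (alpha[i] <= 0.0) continue;
      double d2 = 0.0;
      for (int k = 0; k < p; ++k) {
        double d = Xtrain(i, k) - Xnew(q, k);
        d2 += d * d;
      }
      s += alpha[i] * y[i] * std::exp(-gamma * d2);
    }
    out[q] = s;
  }
  return out;
}
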
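#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Weighted C-SVC solved by SMO with first-order maximal-violating-pair
// working-set selection.  Deterministic: no randomness, ties resolved by
// lowest index.  Dual: min 1/2 a'Qa - e'a, 0 <= a_i <= C_i, y'a = 0,
// Q_ij = y_i y_j K_ij, K = RBF(gamma).

static inline double rbf(const double *xi, const double *xj, int d, int n,
                         double gamma) {
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    double diff = xi[(size_t)k * n] - xj[(size_t)k * n];
    s += diff * diff;
  }
  return std::exp(-gamma * s);
}

// [[Rcpp::export]]
List svm_smo_fit(NumericMatrix X, IntegerVector y, NumericVector Cvec,
                 double gamma, double eps = 1e-3, int max_iter = 100000) {
  const int n = X.nrow(), d = X.ncol();
  if (n != y.size() || n != Cvec.size())
    stop("svm_smo_fit: dimension mismatch");

  std::vector<double> K((size_t)n * n);
  const double *xp = X.begin();
  for (int i = 0; i < n; ++i) {
    K[(size_t)i * n + i] = 1.0;
    for (int j = i + 1; j < n; ++j) {
      double v = rbf(xp + i, xp + j, d, n, gamma);
      K[(size_t)i * n + j] = v;
      K[(size_t)j * n + i] = v;
    }
  }

  std::vector<double> alpha(n, 0.0), G(n, -1.0);
  int iter = 0;
  double gap = R_PosInf;

  while (iter < max_iter) {
    // working set: i maximizes -y_t G_t over I_up, j minimizes over I_low
    int i = -1, j = -1;
    double m = -R_PosInf, M = R_PosInf;
    for (int t = 0; t < n; ++t) {
      double v = -y[t] * G[t];
      bool up = (y[t] == 1) ? (alpha[t] < Cvec[t]) : (alpha[t] > 0);
      bool lo = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < Cvec[t]);
      if (up && v > m) { m = v; i = t; }
      if (lo && v < M) { M = v; j = t; }
    }
    gap = m - M;
    if (i < 0 || j < 0 || gap < eps) break;

    const double Ci = Cvec[i], Cj = Cvec[j];
    const double Kii = K[(size_t)i * n + i], Kjj = K[(size_t)j * n + j],
                 Kij = K[(size_t)i * n + j];
    double ai = alpha[i], aj = alpha[j];

    if (y[i] != y[j]) {
      double quad = Kii + Kjj + 2.0 * Kij;
      if (quad <= 0) quad = 1e-12;
      double delta = (-G[i] - G[j]) / quad;
      double diff = ai - aj;
      ai += delta; aj += delta;
      if (diff > 0) { if (aj < 0) { aj = 0; ai = diff; } }
      else          { if (ai < 0) { ai = 0; aj = -diff; } }
      if (diff > Ci - Cj) { if (ai > Ci) { ai = Ci; aj = Ci - diff; } }
      else                { if (aj > Cj) { aj = Cj; ai = Cj + diff; } }
    } else {
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = 1e-12;
      double delta = (G[i] - G[j]) / quad;
      double sum = ai + aj;
      ai -= delta; aj += delta;
      if (sum > Ci) { if (ai > Ci) { ai = Ci; aj = sum - Ci; } }
      else          { if (aj < 0)  { aj = 0;  ai = sum; } }
      if (sum > Cj) { if (aj > Cj) { aj = Cj; ai = sum - Cj; } }
      else          { if (ai < 0)  { ai = 0;  aj = sum; } }
    }

    double dai = ai - alpha[i], daj = aj - alpha[j];
    alpha[i] = ai; alpha[j] = aj;
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K[(size_t)i * n + t] * dai +
                      y[j] * K[(size_t)j * n + t] * daj);
    ++iter;
  }

  // intercept from free support vectors, else midpoint of the violation band
  double bsum = 0.0; int nfree = 0;
  double m2 = -R_PosInf, M2 = R_PosInf;
  for (int t = 0; t < n; ++t) {
    double v = -y[t] * G[t];
    if (alpha[t] > 1e-12 && alpha[t] < Cvec[t] - 1e-12) { bsum += v; ++nfree; }
    bool up = (y[t] == 1) ? (alpha[t] < Cvec[t]) : (alpha[t] > 0);
    bool lo = (y[t] == 1) ? (alpha[t] > 0) : (alpha[t] < Cvec[t]);
    if (up && v > m2) m2 = v;
    if (lo && v < M2) M2 = v;
  }
  double b = (nfree > 0) ? bsum / nfree : (m2 + M2) / 2.0;

  return List::create(_["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["b"] = b, _["iter"] = iter, _["gap"] = gap);
}

// [[Rcpp::export]]
NumericVector svm_decision_cpp(NumericMatrix Xtrain, IntegerVector y,
                               NumericVector alpha, double b, double gamma,
                               NumericMatrix Xnew) {
  const int n = Xtrain.nrow(), d = Xtrain.ncol(), m = Xnew.nrow();
  if (Xnew.ncol() != d) stop("svm_decision: feature dimension mismatch");
  NumericVector out(m);
  for (int q = 0; q < m; ++q) {
    double f = b;
    for (int i = 0; i < n; ++i) {
      if (alpha[i] <= 0) continue;
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = Xtrain(i, k) - Xnew(q, k);
        s += diff * diff;
      }
      f += alpha[i] * y[i] * std::exp(-gamma * s);
    }
    out[q] = f;
  }
  return out;
}
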
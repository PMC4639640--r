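// Weighted C-SVC with RBF kernel, trained by SMO with maximal-violating-pair
// working-set selection (the classical LIBSVM scheme, reimplemented because
// no SVM library is available in the target environment).
//
// Problem: min_alpha 0.5 a'Qa - e'a, 0 <= a_i <= C_i, Q_ij = y_i y_j K_ij,
// with per-class box constraints C_i implementing class weighting.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline double rbf(const arma::rowvec& a, const arma::rowvec& b,
                         double gamma) {
  double d = arma::accu(arma::square(a - b));
  return std::exp(-gamma * d);
}

// [[Rcpp::export(name = ".rbf_kernel_cpp")]]
arma::mat rbf_kernel_cpp(const arma::mat& X, double gamma) {
  arma::vec sq = arma::sum(arma::square(X), 1);
  arma::mat K = X * X.t();
  const arma::uword n = X.n_rows;
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = 0; j < n; ++j)
      K(i, j) = std::exp(-gamma * (sq(i) + sq(j) - 2.0 * K(i, j)));
  return K;
}

// [[Rcpp::export(name = ".rbf_cross_cpp")]]
arma::mat rbf_cross_cpp(const arma::mat& Xtr, const arma::mat& Xnew,
                        double gamma) {
  arma::vec sa = arma::sum(arma::square(Xnew), 1);
  arma::vec sb = arma::sum(arma::square(Xtr), 1);
  arma::mat K = Xnew * Xtr.t();
  for (arma::uword i = 0; i < K.n_rows; ++i)
    for (arma::uword j = 0; j < K.n_cols; ++j)
      K(i, j) = std::exp(-gamma * (sa(i) + sb(j) - 2.0 * K(i, j)));
  return K;
}

// [[Rcpp::export(name = ".smo_train_cpp")]]
List smo_train_cpp(const arma::mat& K, const arma::vec& y,
                   const arma::vec& C, double eps, int max_iter) {
  const int n = K.n_rows;
  arma::vec alpha(n, arma::fill::zeros);
  arma::vec G(n, arma::fill::ones);
  G *= -1.0; // G_i = sum_j Q_ij a_j - 1 starts at -1
  const double TAU = 1e-12;

  int iter = 0;
  for (; iter < max_iter; ++iter) {
    // working-set selection: maximal violating pair on -y_t G_t
    int i = -1, j = -1;
    double Gmax = -std::numeric_limits<double>::infinity();
    double Gmin = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool up = (y(t) > 0) ? (alpha(t) < C(t)) : (alpha(t) > 0);
      bool low = (y(t) > 0) ? (alpha(t) > 0) : (alpha(t) < C(t));
      double v = -y(t) * G(t);
      if (up && v > Gmax) { Gmax = v; i = t; }
      if (low && v < Gmin) { Gmin = v; j = t; }
    }
    if (i < 0 || j < 0 || Gmax - Gmin < eps) break;

    double Kii = K(i, i), Kjj = K(j, j), Kij = K(i, j);
    double ai_old = alpha(i), aj_old = alpha(j);
    if (y(i) != y(j)) {
      double quad = Kii + Kjj + 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (-G(i) - G(j)) / quad;
      double diff = alpha(i) - alpha(j);
      alpha(i) += delta; alpha(j) += delta;
      if (diff > 0) {
        if (alpha(j) < 0) { alpha(j) = 0; alpha(i) = diff; }
      } else {
        if (alpha(i) < 0) { alpha(i) = 0; alpha(j) = -diff; }
      }
      if (diff > C(i) - C(j)) {
        if (alpha(i) > C(i)) { alpha(i) = C(i); alpha(j) = C(i) - diff; }
      } else {
        if (alpha(j) > C(j)) { alpha(j) = C(j); alpha(i) = C(j) + diff; }
      }
    } else {
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (G(i) - G(j)) / quad;
      double sum = alpha(i) + alpha(j);
      alpha(i) -= delta; alpha(j) += delta;
      if (sum > C(i)) {
        if (alpha(i) > C(i)) { alpha(i) = C(i); alpha(j) = sum - C(i); }
      } else {
        if (alpha(j) < 0) { alpha(j) = 0; alpha(i) = sum; }
      }
      if (sum > C(j)) {
        if (alpha(j) > C(j)) { alpha(j) = C(j); alpha(i) = sum - C(j); }
      } else {
        if (alpha(i) < 0) { alpha(i) = 0; alpha(j) = sum; }
      }
    }
    double dai = alpha(i) - ai_old, daj = alpha(j) - aj_old;
    if (dai == 0.0 && daj == 0.0) break;
    for (int t = 0; t < n; ++t)
      G(t) += y(t) * (y(i) * K(t, i) * dai + y(j) * K(t, j) * daj);
  }

  // intercept: b = -y_t G_t at any free support vector (averaged);
  // if none is free, midpoint of the feasible interval from the
  // up/low sets at termination.
  double bsum = 0.0; int nfree = 0;
  double vup = -std::numeric_limits<double>::infinity();
  double vlow = std::numeric_limits<double>::infinity();
  for (int t = 0; t < n; ++t) {
    double v = -y(t) * G(t);
    if (alpha(t) > TAU && alpha(t) < C(t) - TAU) { bsum += v; ++nfree; }
    bool up = (y(t) > 0) ? (alpha(t) < C(t)) : (alpha(t) > 0);
    bool low = (y(t) > 0) ? (alpha(t) > 0) : (alpha(t) < C(t));
    if (up && v > vup) vup = v;
    if (low && v < vlow) vlow = v;
  }
  double b = (nfree > 0) ? bsum / nfree : (vup + vlow) / 2.0;
  return List::create(_["alpha"] = alpha, _["b"] = b,
                      _["iterations"] = iter,
                      _["converged"] = (iter < max_iter));
}
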
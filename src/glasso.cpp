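#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Block coordinate-descent graphical lasso (Friedman-style) with an
// UNPENALIZED diagonal: the estimate maximizes
//   log det(Theta) - tr(S Theta) - lambda * sum_{i != j} |Theta_ij|
// so W = Theta^{-1} satisfies W_jj = S_jj at the optimum.
//
// W is the working covariance estimate, B(k, j) holds the lasso
// coefficients of the column-j subproblem. Exact zeros in B propagate to
// exact zeros in Theta, so edge support needs no thresholding.
//
// [[Rcpp::export(name = ".glassoCpp")]]
List glassoCpp(NumericMatrix S, double lambda, double tol, int maxIter,
               Nullable<NumericMatrix> warmW = R_NilValue,
               Nullable<NumericMatrix> warmB = R_NilValue) {
  const int p = S.nrow();
  NumericMatrix W(p, p), B(p, p);
  if (warmW.isNotNull()) {
    W = clone(NumericMatrix(warmW.get()));
  } else {
    W = clone(S);
  }
  if (warmB.isNotNull()) B = clone(NumericMatrix(warmB.get()));
  for (int j = 0; j < p; ++j) W(j, j) = S(j, j); // diagonal never penalized

  // relative tolerance scale: mean |off-diagonal of S|
  double sbar = 0.0;
  for (int i = 0; i < p; ++i)
    for (int j = 0; j < p; ++j)
      if (i != j) sbar += std::fabs(S(i, j));
  int noff = p * (p - 1);
  sbar = (noff > 0 && sbar > 0.0) ? sbar / noff : 1.0;
  const double thr = tol * sbar;
  const double innerThr = thr * 0.05;

  bool converged = (p == 1);
  double gap = 0.0;
  int it = 0;
  for (it = 0; it < maxIter && !converged; ++it) {
    double dw = 0.0;
    for (int j = 0; j < p; ++j) {
      // lasso on column j: min 1/2 b' W11 b - s12' b + lambda |b|_1
      for (int inner = 0; inner < 2000; ++inner) {
        double dmax = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double r = S(k, j);
          for (int l = 0; l < p; ++l) {
            if (l == j || l == k) continue;
            r -= W(k, l) * B(l, j);
          }
          double bk = 0.0;
          if (r > lambda) bk = (r - lambda) / W(k, k);
          else if (r < -lambda) bk = (r + lambda) / W(k, k);
          double d = std::fabs(bk - B(k, j));
          if (d > dmax) dmax = d;
          B(k, j) = bk;
        }
        if (dmax < innerThr) break;
      }
      for (int k = 0; k < p; ++k) { // w12 = W11 beta
        if (k == j) continue;
        double w = 0.0;
        for (int l = 0; l < p; ++l) {
          if (l == j) continue;
          w += W(k, l) * B(l, j);
        }
        dw += std::fabs(w - W(k, j));
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    gap = (noff > 0) ? dw / noff : 0.0;
    if (gap < thr) converged = true;
  }

  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; ++j) {
    double q = W(j, j);
    for (int k = 0; k < p; ++k)
      if (k != j) q -= W(k, j) * B(k, j);
    const double tjj = 1.0 / q;
    Theta(j, j) = tjj;
    for (int k = 0; k < p; ++k)
      if (k != j) Theta(k, j) = -B(k, j) * tjj;
  }
  // symmetrize, preserving exact-zero support
  for (int i = 0; i < p; ++i)
    for (int j = i + 1; j < p; ++j) {
      double a = Theta(i, j), b = Theta(j, i);
      double v = (a == 0.0 || b == 0.0) ? 0.0 : 0.5 * (a + b);
      Theta(i, j) = v;
      Theta(j, i) = v;
    }

  return List::create(_["Theta"] = Theta, _["W"] = W, _["B"] = B,
                      _["iterations"] = it, _["converged"] = converged,
                      _["gap"] = gap);
}
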
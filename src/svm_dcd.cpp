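#include <Rcpp.h>
using namespace Rcpp;

// Dual coordinate descent for an L2-regularized L1-loss (hinge) linear SVM
// (Hsieh et al. 2008, Algorithm 3), deterministic cyclic order, no
// shrinking. Input is t(X) in compressed sparse column layout, so column j
// holds the feature vector of sample j. The bias is handled by an implicit
// augmented feature of constant value `bias_scale`, which makes the label
// -swap antisymmetry of the solution exact in floating point.
//
// min_w 1/2 ||w||^2 + C sum_i max(0, 1 - y_i (w.x_i + b))

// [[Rcpp::export]]
List svm_dcd(S4 Xt, NumericVector y, double C, int max_iter, double tol,
             double bias_scale) {
  IntegerVector p = Xt.slot("p");
  IntegerVector ri = Xt.slot("i");
  NumericVector xv = Xt.slot("x");
  IntegerVector dims = Xt.slot("Dim");
  int d = dims[0];
  int n = dims[1];
  if (y.size() != n) stop("length(y) != ncol(Xt)");

  std::vector<double> w(d, 0.0);
  double wb = 0.0;
  std::vector<double> alpha(n, 0.0);
  std::vector<double> qii(n);
  double b2 = bias_scale * bias_scale;
  for (int i = 0; i < n; ++i) {
    double s = b2;
    for (int t = p[i]; t < p[i + 1]; ++t) s += xv[t] * xv[t];
    qii[i] = s;
  }

  int iter = 0;
  double max_pg = R_PosInf;
  for (iter = 0; iter < max_iter; ++iter) {
    max_pg = 0.0;
    for (int i = 0; i < n; ++i) {
      double dot = wb * bias_scale;
      for (int t = p[i]; t < p[i + 1]; ++t) dot += w[ri[t]] * xv[t];
      double G = y[i] * dot - 1.0;
      double pg;
      if (alpha[i] <= 0.0)       pg = G < 0.0 ? G : 0.0;
      else if (alpha[i] >= C)    pg = G > 0.0 ? G : 0.0;
      else                       pg = G;
      if (std::abs(pg) > max_pg) max_pg = std::abs(pg);
      if (pg != 0.0) {
        double a_old = alpha[i];
        double a_new = a_old - G / qii[i];
        if (a_new < 0.0) a_new = 0.0;
        if (a_new > C) a_new = C;
        alpha[i] = a_new;
        double delta = (a_new - a_old) * y[i];
        if (delta != 0.0) {
          for (int t = p[i]; t < p[i + 1]; ++t) w[ri[t]] += delta * xv[t];
          wb += delta * bias_scale;
        }
      }
    }
    if (max_pg < tol) { ++iter; break; }
  }

  return List::create(_["weights"] = NumericVector(w.begin(), w.end()),
                      _["bias"] = wb * bias_scale,
                      _["alpha"] = NumericVector(alpha.begin(), alpha.end()),
                      _["iterations"] = iter,
                      _["max_pg"] = max_pg,
                      _["converged"] = max_pg < tol);
}
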
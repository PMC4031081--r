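#include <Rcpp.h>
using namespace Rcpp;

// Cyclic coordinate descent for the non-negative L1-penalized least squares
// problem
//
//   min_{m >= 0}  || c - K m ||^2  +  lambda * sum_j m_j
//
// parameterized by the Gram matrix G = K'K and the projection b = K'c.
// Because m is constrained non-negative the L1 term is linear, so every
// coordinate update has a closed form:
//
//   m_j <- max(0, (b_j - lambda/2 - sum_{k != j} G_jk m_k) / G_jj)
//
// The running product q = G m is updated incrementally, giving O(p) work per
// coordinate. `tol` is an absolute threshold on the largest coordinate change
// in one sweep; the caller scales it with the data.
// [[Rcpp::export]]
List cd_nnls_l1(const NumericMatrix& gram, const NumericVector& b,
                double lambda, int max_iter, double tol,
                const NumericVector& start) {
  const int p = b.size();
  if (gram.nrow() != p || gram.ncol() != p)
    stop("gram matrix dimensions do not match b");
  NumericVector m = clone(start);
  NumericVector q(p);  // q = G m
  for (int j = 0; j < p; ++j) {
    const double mj = m[j];
    if (mj != 0.0) {
      NumericMatrix::ConstColumn col = gram(_, j);
      for (int i = 0; i < p; ++i) q[i] += col[i] * mj;
    }
  }
  const double half_lambda = lambda / 2.0;
  double delta = R_PosInf;
  int it = 0;
  while (it < max_iter && delta > tol) {
    delta = 0.0;
    for (int j = 0; j < p; ++j) {
      const double gjj = gram(j, j);
      if (gjj <= 0.0) continue;
      const double num = b[j] - half_lambda - (q[j] - gjj * m[j]);
      double mj = num / gjj;
      if (mj < 0.0) mj = 0.0;
      const double d = mj - m[j];
      if (d != 0.0) {
        NumericMatrix::ConstColumn col = gram(_, j);
        for (int i = 0; i < p; ++i) q[i] += col[i] * d;
        m[j] = mj;
        const double ad = d < 0 ? -d : d;
        if (ad > delta) delta = ad;
      }
    }
    ++it;
  }
  return List::create(_["coefficients"] = m,
                      _["iterations"] = it,
                      _["converged"] = delta <= tol);
}
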
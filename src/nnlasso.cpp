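#include <Rcpp.h>
using namespace Rcpp;

// Non-negative L1-regularized least squares by cyclic coordinate descent.
//
// Solves, for each column b of B:
//   min_x  1/2 x'Gx - b'x + lambda * sum(x)   s.t.  x >= 0
// which is 1/2 ||D x - y||_2^2 + lambda ||x||_1 + const with G = D'D and
// b = D'y (x >= 0 makes |x|_1 = sum(x)). Deterministic: x starts at 0 and
// coordinates are swept in order. Convergence when the relative objective
// decrease over a full sweep falls below `tol`, or after `maxit` sweeps.
//
// Returns the c x m solution matrix and the per-column partial objective
// 1/2 x'Gx - b'x + lambda*sum(x) (the caller adds 1/2||y||^2).
// [[Rcpp::export]]
List nnlasso_cd_batch(NumericMatrix G, NumericMatrix B, double lambda,
                      double tol, int maxit) {
  const int c = G.nrow(), m = B.ncol();
  NumericMatrix X(c, m);
  NumericVector obj(m), iters(m);
  std::vector<double> q(c);  // q = G x, maintained incrementally

  for (int col = 0; col < m; ++col) {
    std::fill(q.begin(), q.end(), 0.0);
    double objPrev = 0.0;  // objective at x = 0
    int it = 0;
    for (it = 1; it <= maxit; ++it) {
      for (int j = 0; j < c; ++j) {
        const double gjj = G(j, j);
        if (gjj <= 0.0) continue;
        const double xold = X(j, col);
        // minimize the 1-d quadratic in x_j with the rest fixed
        double xnew = (B(j, col) - lambda - (q[j] - gjj * xold)) / gjj;
        if (xnew < 0.0) xnew = 0.0;
        const double delta = xnew - xold;
        if (delta != 0.0) {
          X(j, col) = xnew;
          for (int i = 0; i < c; ++i) q[i] += delta * G(i, j);
        }
      }
      double objNow = 0.0;
      for (int j = 0; j < c; ++j)
        objNow += 0.5 * X(j, col) * q[j] - B(j, col) * X(j, col)
                  + lambda * X(j, col);
      if (it > 1 && std::abs(objPrev - objNow)
                      <= tol * std::max(1.0, std::abs(objPrev)))
        { objPrev = objNow; break; }
      objPrev = objNow;
    }
    obj[col] = objPrev;
    iters[col] = it;
  }
  return List::create(_["x"] = X, _["objective"] = obj,
                      _["sweeps"] = iters);
}
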
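#include <Rcpp.h>
using namespace Rcpp;

// Self-consistent fixed-point iteration for the reversible (detailed-
// balance constrained) maximum-likelihood transition matrix.
// Csym = C + t(C); ci = rowSums(C).  Iterates the symmetric flux matrix
// x_ij <- (c_ij + c_ji) / (c_i/x_i + c_j/x_j) until the stationary
// distribution (row sums of normalised X) moves less than tol.
// Returns X (normalised); attribute "iterations" records the count,
// "converged" the status.
// [[Rcpp::export]]
NumericMatrix reversible_mle_cpp(NumericMatrix Csym, NumericVector ci,
                                 double tol, int max_iter) {
  const int n = Csym.nrow();
  NumericMatrix X(n, n);
  double tot = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) tot += Csym(i, j);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) X(i, j) = Csym(i, j) / tot;

  std::vector<double> xi(n), pi_old(n), pi_new(n);
  bool converged = false;
  int it = 0;
  double res = R_PosInf;
  for (int i = 0; i < n; ++i) {
    double s = 0.0;
    for (int j = 0; j < n; ++j) s += X(i, j);
    pi_old[i] = s;
  }
  for (it = 0; it < max_iter; ++it) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += X(i, j);
      xi[i] = s;
    }
    double newtot = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int j = i; j < n; ++j) {
        double c = Csym(i, j);
        double v = (c > 0.0) ? c / (ci[i] / xi[i] + ci[j] / xi[j]) : 0.0;
        X(i, j) = v;
        X(j, i) = v;
        newtot += (i == j) ? v : 2.0 * v;
      }
    }
    res = 0.0;
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += X(i, j);
      pi_new[i] = s / newtot;
      double d = std::fabs(pi_new[i] - pi_old[i]);
      if (d > res) res = d;
      pi_old[i] = pi_new[i];
    }
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) X(i, j) /= newtot;
    if (res < tol) { converged = true; break; }
  }
  X.attr("iterations") = it + 1;
  X.attr("converged") = converged;
  X.attr("residual") = res;
  return X;
}
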
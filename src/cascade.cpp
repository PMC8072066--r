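#include <Rcpp.h>
using namespace Rcpp;

// Analytic solution of the linear differentiation cascade
//   dy_1/dt = -kappa_1 y_1
//   dy_i/dt = alpha_{i-1} y_{i-1} - kappa_i y_i   (i > 1)
// for pairwise-distinct kappa, as a sum of exponentials:
//   y_i(t) = sum_{j<=i} A_ij exp(-kappa_j t)
// with A_ij = alpha_{i-1} A_{i-1,j} / (kappa_i - kappa_j) for j < i and
// A_ii fixed by the initial condition. alpha[i] is the differentiation
// rate of compartment i+1 (0-based); the last entry is unused here.
// Degeneracy handling (perturbation of tied kappa) is done by the R caller.

// [[Rcpp::export]]
NumericMatrix cascade_solve_cpp(NumericVector kappa, NumericVector alpha,
                                NumericVector y0, NumericVector times) {
  const int K = kappa.size();
  const int T = times.size();
  NumericMatrix A(K, K);
  for (int i = 0; i < K; ++i) {
    double rowsum = 0.0;
    for (int j = 0; j < i; ++j) {
      A(i, j) = alpha[i - 1] * A(i - 1, j) / (kappa[i] - kappa[j]);
      rowsum += A(i, j);
    }
    A(i, i) = y0[i] - rowsum;
  }
  NumericMatrix out(T, K);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < K; ++i) {
      double v = 0.0;
      for (int j = 0; j <= i; ++j)
        v += A(i, j) * std::exp(-kappa[j] * times[t]);
      out(t, i) = v;
    }
  }
  return out;
}
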
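#include <Rcpp.h>
using namespace Rcpp;

// Weighted SSR of one dataset against the cascade model, fully in C++ for
// the optimizer's hot path. Observable columns (K = 4 chain with the
// first two compartments forming the observed HSC gate):
//   1 aggregate HSC labeled frequency
//   2 ST-HSC labeled frequency normalized to the HSC frequency
//   3 MPP labeled frequency normalized to the HSC frequency
//   4 aggregate HSC count, 5 ST-HSC count, 6 MPP count
// ti is the 1-based index into `times` for each observation.
// Returns 1e12 on any non-finite prediction (optimizer penalty).

static void cascade_coef(const std::vector<double>& kappa,
                         const NumericVector& alpha,
                         const std::vector<double>& y0,
                         std::vector<double>& A, int K) {
  for (int i = 0; i < K; ++i) {
    double rowsum = 0.0;
    for (int j = 0; j < i; ++j) {
      A[i * K + j] = alpha[i - 1] * A[(i - 1) * K + j] /
                     (kappa[i] - kappa[j]);
      rowsum += A[i * K + j];
    }
    A[i * K + i] = y0[i] - rowsum;
  }
}

// [[Rcpp::export]]
double obs_ssr_cpp(NumericVector kappa_in, NumericVector alpha,
                   NumericVector n0, NumericVector f0,
                   NumericVector times, IntegerVector ti,
                   IntegerVector col, NumericVector y,
                   NumericVector sem) {
  const int K = kappa_in.size();
  const int T = times.size();
  std::vector<double> kappa(kappa_in.begin(), kappa_in.end());
  // perturb tied decay rates (transient optimizer proposals)
  for (bool tied = true; tied;) {
    tied = false;
    for (int i = 0; i < K && !tied; ++i)
      for (int j = i + 1; j < K && !tied; ++j)
        if (std::fabs(kappa[i] - kappa[j]) < 1e-9) {
          kappa[i] += 1e-9;
          tied = true;
        }
  }
  std::vector<double> An(K * K), Al(K * K), y0n(K), y0l(K);
  for (int i = 0; i < K; ++i) {
    y0n[i] = n0[i];
    y0l[i] = f0[i] * n0[i];
  }
  cascade_coef(kappa, alpha, y0n, An, K);
  cascade_coef(kappa, alpha, y0l, Al, K);

  // 6 observable columns per time point
  std::vector<double> P(T * 6);
  std::vector<double> e(K);
  for (int t = 0; t < T; ++t) {
    double n[4], l[4];
    for (int j = 0; j < K; ++j) e[j] = std::exp(-kappa[j] * times[t]);
    for (int i = 0; i < K; ++i) {
      double vn = 0.0, vl = 0.0;
      for (int j = 0; j <= i; ++j) {
        vn += An[i * K + j] * e[j];
        vl += Al[i * K + j] * e[j];
      }
      n[i] = vn;
      l[i] = vl;
    }
    const double nH = n[0] + n[1];
    const double fH = (l[0] + l[1]) / nH;
    P[t * 6 + 0] = fH;
    P[t * 6 + 1] = (l[2] / n[2]) / fH;
    P[t * 6 + 2] = (l[3] / n[3]) / fH;
    P[t * 6 + 3] = nH;
    P[t * 6 + 4] = n[2];
    P[t * 6 + 5] = n[3];
  }
  double ssr = 0.0;
  const int M = y.size();
  for (int m = 0; m < M; ++m) {
    const double pred = P[(ti[m] - 1) * 6 + (col[m] - 1)];
    if (!std::isfinite(pred)) return 1e12;
    const double r = (pred - y[m]) / sem[m];
    ssr += r * r;
  }
  if (!std::isfinite(ssr)) return 1e12;
  return ssr;
}
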
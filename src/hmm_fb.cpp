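#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a 2-state HMM on one chromosome.
// logEmiss: T x 2 matrix of log emission densities; trans: 2x2 row-stochastic;
// initP: length-2 initial distribution. Returns the per-position posterior
// (gamma), the summed pairwise posteriors (xi) for the transition M-step, and
// the log-likelihood.
// [[Rcpp::export(name = ".fbScaled")]]
List fbScaled(NumericMatrix logEmiss, NumericMatrix trans, NumericVector initP) {
  const int T = logEmiss.nrow();
  const int K = 2;
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector scale(T), mshift(T);
  NumericMatrix b(T, K);

  for (int t = 0; t < T; ++t) {
    double m = std::max(logEmiss(t, 0), logEmiss(t, 1));
    if (!R_finite(m)) m = 0.0;
    mshift[t] = m;
    for (int k = 0; k < K; ++k) {
      double e = std::exp(logEmiss(t, k) - m);
      b(t, k) = (R_finite(e) ? e : 0.0);
    }
  }

  // forward
  double c0 = 0.0;
  for (int k = 0; k < K; ++k) {
    alpha(0, k) = initP[k] * b(0, k);
    c0 += alpha(0, k);
  }
  if (c0 <= 0) c0 = 1e-300;
  for (int k = 0; k < K; ++k) alpha(0, k) /= c0;
  scale[0] = c0;
  for (int t = 1; t < T; ++t) {
    double ct = 0.0;
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += alpha(t - 1, j) * trans(j, k);
      alpha(t, k) = s * b(t, k);
      ct += alpha(t, k);
    }
    if (ct <= 0) ct = 1e-300;
    for (int k = 0; k < K; ++k) alpha(t, k) /= ct;
    scale[t] = ct;
  }

  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double s = 0.0;
      for (int j = 0; j < K; ++j)
        s += trans(k, j) * b(t + 1, j) * beta(t + 1, j);
      beta(t, k) = s / scale[t + 1];
    }
  }

  // gamma and xi sums
  NumericMatrix xi(K, K);
  for (int t = 0; t < T; ++t) {
    double norm = 0.0;
    for (int k = 0; k < K; ++k) {
      gamma(t, k) = alpha(t, k) * beta(t, k);
      norm += gamma(t, k);
    }
    if (norm <= 0) norm = 1e-300;
    for (int k = 0; k < K; ++k) gamma(t, k) /= norm;
  }
  for (int t = 0; t + 1 < T; ++t) {
    double norm = 0.0;
    double tmp[2][2];
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) {
        tmp[j][k] = alpha(t, j) * trans(j, k) * b(t + 1, k) * beta(t + 1, k);
        norm += tmp[j][k];
      }
    if (norm <= 0) norm = 1e-300;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k) xi(j, k) += tmp[j][k] / norm;
  }

  double ll = 0.0;
  for (int t = 0; t < T; ++t) ll += std::log(scale[t]) + mshift[t];

  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["logLik"] = ll);
}
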
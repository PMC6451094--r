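#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward pass for a Gaussian-emission HMM.
// obs: T observations; pi: K initial probs; A: KxK row-stochastic transition
// matrix; mu, sigma: K emission means/SDs. Returns log-likelihood, the
// per-frame posteriors gamma (TxK) and the summed transition posteriors
// xi_sum (KxK), i.e. everything the Baum-Welch M-step needs.
// [[Rcpp::export]]
List hmm_forward_backward(NumericVector obs, NumericVector pi, NumericMatrix A,
                          NumericVector mu, NumericVector sigma) {
  const int T = obs.size(), K = pi.size();
  NumericMatrix B(T, K);      // emission densities
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
  NumericVector c(T);         // per-frame scaling factors
  NumericMatrix xi_sum(K, K);

  for (int t = 0; t < T; ++t)
    for (int k = 0; k < K; ++k)
      B(t, k) = R::dnorm(obs[t], mu[k], sigma[k], 0) + 1e-300;

  // forward
  double s = 0.0;
  for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
  c[0] = s;
  for (int k = 0; k < K; ++k) alpha(0, k) /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double a = 0.0;
      for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
      alpha(t, k) = a * B(t, k);
      s += alpha(t, k);
    }
    c[t] = s;
    for (int k = 0; k < K; ++k) alpha(t, k) /= s;
  }

  // backward
  for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    for (int k = 0; k < K; ++k) {
      double b = 0.0;
      for (int j = 0; j < K; ++j) b += A(k, j) * B(t + 1, j) * beta(t + 1, j);
      beta(t, k) = b / c[t + 1];
    }
  }

  double loglik = 0.0;
  for (int t = 0; t < T; ++t) loglik += std::log(c[t]);

  for (int t = 0; t < T; ++t) {
    double g = 0.0;
    for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
    for (int k = 0; k < K; ++k) gamma(t, k) /= g;
  }

  for (int t = 0; t < T - 1; ++t) {
    double denom = 0.0;
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        denom += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k);
    for (int j = 0; j < K; ++j)
      for (int k = 0; k < K; ++k)
        xi_sum(j, k) += alpha(t, j) * A(j, k) * B(t + 1, k) * beta(t + 1, k) / denom;
  }

  return List::create(_["loglik"] = loglik, _["gamma"] = gamma,
                      _["xi_sum"] = xi_sum);
}

// Forward log-likelihood only (scaled recursion).
// [[Rcpp::export]]
double hmm_loglik(NumericVector obs, NumericVector pi, NumericMatrix A,
                  NumericVector mu, NumericVector sigma) {
  const int T = obs.size(), K = pi.size();
  std::vector<double> a(K), anew(K);
  double loglik = 0.0, s = 0.0;
  for (int k = 0; k < K; ++k) {
    a[k] = pi[k] * (R::dnorm(obs[0], mu[k], sigma[k], 0) + 1e-300);
    s += a[k];
  }
  loglik += std::log(s);
  for (int k = 0; k < K; ++k) a[k] /= s;
  for (int t = 1; t < T; ++t) {
    s = 0.0;
    for (int k = 0; k < K; ++k) {
      double x = 0.0;
      for (int j = 0; j < K; ++j) x += a[j] * A(j, k);
      anew[k] = x * (R::dnorm(obs[t], mu[k], sigma[k], 0) + 1e-300);
      s += anew[k];
    }
    loglik += std::log(s);
    for (int k = 0; k < K; ++k) a[k] = anew[k] / s;
  }
  return loglik;
}

// Viterbi decoding in log space; returns 1-based state path and its
// joint log-probability.
// [[Rcpp::export]]
List hmm_viterbi(NumericVector obs, NumericVector pi, NumericMatrix A,
                 NumericVector mu, NumericVector sigma) {
  const int T = obs.size(), K = pi.size();
  NumericMatrix logd(T, K);
  IntegerMatrix back(T, K);
  NumericMatrix logA(K, K);
  for (int j = 0; j < K; ++j)
    for (int k = 0; k < K; ++k)
      logA(j, k) = std::log(A(j, k) + 1e-300);

  for (int k = 0; k < K; ++k)
    logd(0, k) = std::log(pi[k] + 1e-300) + R::dnorm(obs[0], mu[k], sigma[k], 1);
  for (int t = 1; t < T; ++t) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf; int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = logd(t - 1, j) + logA(j, k);
        if (v > best) { best = v; arg = j; }
      }
      logd(t, k) = best + R::dnorm(obs[t], mu[k], sigma[k], 1);
      back(t, k) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int k = 0; k < K; ++k)
    if (logd(T - 1, k) > best) { best = logd(T - 1, k); arg = k; }
  path[T - 1] = arg;
  for (int t = T - 1; t > 0; --t) path[t - 1] = back(t, path[t]);
  for (int t = 0; t < T; ++t) path[t] += 1;
  return List::create(_["path"] = path, _["logprob"] = best);
}
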
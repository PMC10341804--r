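#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward pass over one chromosome.
// logB: T x K matrix of per-bin log emission probabilities.
// Returns the log-likelihood of the sequence.
// [[Rcpp::export]]
double hmm_forward_loglik_cpp(NumericMatrix logB, NumericVector init,
                              NumericMatrix trans) {
  const int T = logB.nrow(), K = logB.ncol();
  std::vector<double> alpha(K), tmp(K);
  double loglik = 0.0;

  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, logB(t, k));
    if (t == 0) {
      for (int k = 0; k < K; ++k) alpha[k] = init[k] * std::exp(logB(t, k) - m);
    } else {
      for (int j = 0; j < K; ++j) {
        double s = 0.0;
        for (int i = 0; i < K; ++i) s += alpha[i] * trans(i, j);
        tmp[j] = s * std::exp(logB(t, j) - m);
      }
      std::copy(tmp.begin(), tmp.end(), alpha.begin());
    }
    double norm = 0.0;
    for (int k = 0; k < K; ++k) norm += alpha[k];
    if (norm <= 0.0) return R_NegInf;
    for (int k = 0; k < K; ++k) alpha[k] /= norm;
    loglik += std::log(norm) + m;
  }
  return loglik;
}

// Scaled forward-backward E-step over one chromosome.
// Returns per-bin posteriors gamma (T x K), summed transition posteriors
// xi_sum (K x K) and the log-likelihood.
// [[Rcpp::export]]
List hmm_forward_backward_cpp(NumericMatrix logB, NumericVector init,
                              NumericMatrix trans) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix b(T, K), alpha(T, K), gamma(T, K);
  NumericMatrix xi_sum(K, K);
  std::vector<double> scale(T), m(T), beta(K), beta_new(K);
  double loglik = 0.0;

  for (int t = 0; t < T; ++t) {
    double mx = logB(t, 0);
    for (int k = 1; k < K; ++k) mx = std::max(mx, logB(t, k));
    m[t] = mx;
    for (int k = 0; k < K; ++k) b(t, k) = std::exp(logB(t, k) - mx);
  }

  for (int t = 0; t < T; ++t) {
    if (t == 0) {
      for (int k = 0; k < K; ++k) alpha(0, k) = init[k] * b(0, k);
    } else {
      for (int j = 0; j < K; ++j) {
        double s = 0.0;
        for (int i = 0; i < K; ++i) s += alpha(t - 1, i) * trans(i, j);
        alpha(t, j) = s * b(t, j);
      }
    }
    double norm = 0.0;
    for (int k = 0; k < K; ++k) norm += alpha(t, k);
    if (norm <= 0.0) stop("forward pass underflow: impossible observation");
    for (int k = 0; k < K; ++k) alpha(t, k) /= norm;
    scale[t] = norm;
    loglik += std::log(norm) + m[t];
  }

  for (int k = 0; k < K; ++k) beta[k] = 1.0;
  for (int k = 0; k < K; ++k) gamma(T - 1, k) = alpha(T - 1, k);
  for (int t = T - 2; t >= 0; --t) {
    // xi_t(i,j) proportional to alpha_t(i) A(i,j) b_{t+1}(j) beta_{t+1}(j)
    double xnorm = 0.0;
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xnorm += alpha(t, i) * trans(i, j) * b(t + 1, j) * beta[j];
    if (xnorm > 0.0) {
      for (int i = 0; i < K; ++i)
        for (int j = 0; j < K; ++j)
          xi_sum(i, j) += alpha(t, i) * trans(i, j) * b(t + 1, j) * beta[j] / xnorm;
    }
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += trans(i, j) * b(t + 1, j) * beta[j];
      beta_new[i] = s / scale[t + 1];
    }
    std::copy(beta_new.begin(), beta_new.end(), beta.begin());
    double gnorm = 0.0;
    for (int k = 0; k < K; ++k) gnorm += alpha(t, k) * beta[k];
    for (int k = 0; k < K; ++k) gamma(t, k) = alpha(t, k) * beta[k] / gnorm;
  }

  return List::create(Named("gamma") = gamma, Named("xi_sum") = xi_sum,
                      Named("loglik") = loglik);
}

// Viterbi decoding over one chromosome; returns the 1-based MAP state path.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(NumericMatrix logB, NumericVector log_init,
                              NumericMatrix log_trans) {
  const int T = logB.nrow(), K = logB.ncol();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  for (int k = 0; k < K; ++k) delta(0, k) = log_init[k] + logB(0, k);
  for (int t = 1; t < T; ++t) {
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf;
      int arg = 0;
      for (int i = 0; i < K; ++i) {
        double v = delta(t - 1, i) + log_trans(i, j);
        if (v > best) { best = v; arg = i; }
      }
      delta(t, j) = best + logB(t, j);
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf;
  int arg = 0;
  for (int k = 0; k < K; ++k)
    if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
  path[T - 1] = arg + 1;
  for (int t = T - 1; t > 0; --t) {
    arg = psi(t, arg);
    path[t - 1] = arg + 1;
  }
  return path;
}
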
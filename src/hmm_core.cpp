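#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Scaled forward-backward over many concatenated sequences sharing one
// parameter set.  logB holds log emission densities for every observation
// (rows) and state (columns); lens gives the length of each sequence and
// must sum to nrow(logB).  Emissions are re-centred per row before
// exponentiation so very small densities do not underflow.

// [[Rcpp::export]]
List hmm_estep_cpp(const NumericMatrix& logB, const IntegerVector& lens,
                   const NumericVector& pi, const NumericMatrix& A) {
  const int N = logB.nrow(), K = logB.ncol(), S = lens.size();
  NumericMatrix post(N, K);
  NumericMatrix xi(K, K);
  NumericVector init(K);
  double loglik = 0.0;

  std::vector<double> B(static_cast<size_t>(N) * K);
  std::vector<double> rowmax(N);
  for (int t = 0; t < N; ++t) {
    double m = logB(t, 0);
    for (int k = 1; k < K; ++k) if (logB(t, k) > m) m = logB(t, k);
    rowmax[t] = m;
    for (int k = 0; k < K; ++k)
      B[static_cast<size_t>(t) * K + k] = std::exp(logB(t, k) - m);
  }

  int maxlen = 0;
  for (int s = 0; s < S; ++s) if (lens[s] > maxlen) maxlen = lens[s];
  std::vector<double> alpha(static_cast<size_t>(maxlen) * K);
  std::vector<double> beta(K), beta_next(K), c(maxlen);

  int off = 0;
  for (int s = 0; s < S; ++s) {
    const int T = lens[s];
    // forward pass with per-step scaling
    for (int t = 0; t < T; ++t) {
      const double* Bt = &B[static_cast<size_t>(off + t) * K];
      double csum = 0.0;
      for (int j = 0; j < K; ++j) {
        double a;
        if (t == 0) {
          a = pi[j] * Bt[j];
        } else {
          double acc = 0.0;
          for (int i = 0; i < K; ++i)
            acc += alpha[static_cast<size_t>(t - 1) * K + i] * A(i, j);
          a = acc * Bt[j];
        }
        alpha[static_cast<size_t>(t) * K + j] = a;
        csum += a;
      }
      if (csum <= 0.0 || !std::isfinite(csum))
        stop("forward pass underflow: zero total emission probability");
      c[t] = csum;
      for (int j = 0; j < K; ++j) alpha[static_cast<size_t>(t) * K + j] /= csum;
      loglik += std::log(csum) + rowmax[off + t];
    }
    // backward pass, posteriors and transition expectations
    for (int j = 0; j < K; ++j) beta[j] = 1.0;
    for (int j = 0; j < K; ++j)
      post(off + T - 1, j) = alpha[static_cast<size_t>(T - 1) * K + j];
    for (int t = T - 2; t >= 0; --t) {
      const double* Bt1 = &B[static_cast<size_t>(off + t + 1) * K];
      for (int j = 0; j < K; ++j) beta_next[j] = beta[j];
      for (int i = 0; i < K; ++i) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j) acc += A(i, j) * Bt1[j] * beta_next[j];
        beta[i] = acc / c[t + 1];
      }
      double psum = 0.0;
      for (int i = 0; i < K; ++i) {
        double p = alpha[static_cast<size_t>(t) * K + i] * beta[i];
        post(off + t, i) = p;
        psum += p;
      }
      for (int i = 0; i < K; ++i) post(off + t, i) /= psum;
      for (int i = 0; i < K; ++i) {
        const double ai = alpha[static_cast<size_t>(t) * K + i];
        for (int j = 0; j < K; ++j)
          xi(i, j) += ai * A(i, j) * Bt1[j] * beta_next[j] / c[t + 1];
      }
    }
    for (int j = 0; j < K; ++j) init[j] += post(off, j);
    off += T;
  }
  return List::create(_["loglik"] = loglik, _["post"] = post,
                      _["xi"] = xi, _["init"] = init);
}

// Viterbi decoding of the same concatenated layout; returns 1-based states.

// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(const NumericMatrix& logB, const IntegerVector& lens,
                              const NumericVector& logpi, const NumericMatrix& logA) {
  const int N = logB.nrow(), K = logB.ncol(), S = lens.size();
  IntegerVector path(N);
  int maxlen = 0;
  for (int s = 0; s < S; ++s) if (lens[s] > maxlen) maxlen = lens[s];
  std::vector<double> delta(static_cast<size_t>(maxlen) * K);
  std::vector<int> psi(static_cast<size_t>(maxlen) * K);

  int off = 0;
  for (int s = 0; s < S; ++s) {
    const int T = lens[s];
    for (int j = 0; j < K; ++j) delta[j] = logpi[j] + logB(off, j);
    for (int t = 1; t < T; ++t) {
      for (int j = 0; j < K; ++j) {
        double best = delta[static_cast<size_t>(t - 1) * K] + logA(0, j);
        int arg = 0;
        for (int i = 1; i < K; ++i) {
          const double v = delta[static_cast<size_t>(t - 1) * K + i] + logA(i, j);
          if (v > best) { best = v; arg = i; }
        }
        delta[static_cast<size_t>(t) * K + j] = best + logB(off + t, j);
        psi[static_cast<size_t>(t) * K + j] = arg;
      }
    }
    int arg = 0;
    double best = delta[static_cast<size_t>(T - 1) * K];
    for (int j = 1; j < K; ++j)
      if (delta[static_cast<size_t>(T - 1) * K + j] > best) {
        best = delta[static_cast<size_t>(T - 1) * K + j];
        arg = j;
      }
    path[off + T - 1] = arg + 1;
    for (int t = T - 2; t >= 0; --t) {
      arg = psi[static_cast<size_t>(t + 1) * K + arg];
      path[off + t] = arg + 1;
    }
    off += T;
  }
  return path;
}
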
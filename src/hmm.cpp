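#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Scaled forward-backward over a concatenation of independent runs.
// logdens: T x K log emission densities; the recursion restarts at every run
// boundary (no transition probability is spent across scans).
// Returns posteriors (gamma), summed two-slice statistics (xi_sum), the total
// log-likelihood, and the sum of posterior rows at run starts (for the
// initial-distribution M-step).
// [[Rcpp::export]]
List fb_cpp(const NumericMatrix& logdens, const NumericVector& init,
            const NumericMatrix& trans, const IntegerVector& run_starts,
            const IntegerVector& run_lengths) {
  const int T = logdens.nrow(), K = logdens.ncol(), R = run_starts.size();
  NumericMatrix gamma(T, K), xi(K, K);
  NumericVector start_post(K);
  double loglik = 0.0;
  std::vector<double> alpha((size_t)T * K), scale(T), shift(T), b((size_t)T * K);

  for (int t = 0; t < T; ++t) {
    double m = logdens(t, 0);
    for (int k = 1; k < K; ++k) if (logdens(t, k) > m) m = logdens(t, k);
    shift[t] = m;
    for (int k = 0; k < K; ++k) b[(size_t)t * K + k] = std::exp(logdens(t, k) - m);
  }

  for (int r = 0; r < R; ++r) {
    const int s = run_starts[r] - 1, L = run_lengths[r];
    for (int t = s; t < s + L; ++t) {
      double c = 0.0;
      if (t == s) {
        for (int k = 0; k < K; ++k) {
          alpha[(size_t)t * K + k] = init[k] * b[(size_t)t * K + k];
          c += alpha[(size_t)t * K + k];
        }
      } else {
        for (int k = 0; k < K; ++k) {
          double a = 0.0;
          for (int j = 0; j < K; ++j) a += alpha[(size_t)(t - 1) * K + j] * trans(j, k);
          alpha[(size_t)t * K + k] = a * b[(size_t)t * K + k];
          c += alpha[(size_t)t * K + k];
        }
      }
      if (!(c > 0.0) || !std::isfinite(c))
        stop("numerical underflow in forward recursion at time point %d", t + 1);
      scale[t] = c;
      loglik += std::log(c) + shift[t];
      for (int k = 0; k < K; ++k) alpha[(size_t)t * K + k] /= c;
    }
    std::vector<double> beta(K, 1.0), beta_new(K);
    for (int k = 0; k < K; ++k) gamma(s + L - 1, k) = alpha[(size_t)(s + L - 1) * K + k];
    for (int t = s + L - 2; t >= s; --t) {
      for (int k = 0; k < K; ++k) {
        double v = 0.0;
        for (int j = 0; j < K; ++j)
          v += trans(k, j) * b[(size_t)(t + 1) * K + j] * beta[j];
        beta_new[k] = v / scale[t + 1];
        for (int j = 0; j < K; ++j)
          xi(k, j) += alpha[(size_t)t * K + k] * trans(k, j) *
                      b[(size_t)(t + 1) * K + j] * beta[j] / scale[t + 1];
      }
      double g = 0.0;
      for (int k = 0; k < K; ++k) {
        beta[k] = beta_new[k];
        gamma(t, k) = alpha[(size_t)t * K + k] * beta[k];
        g += gamma(t, k);
      }
      for (int k = 0; k < K; ++k) gamma(t, k) /= g;
    }
    for (int k = 0; k < K; ++k) start_post[k] += gamma(s, k);
  }
  return List::create(_["gamma"] = gamma, _["xi_sum"] = xi,
                      _["loglik"] = loglik, _["start_post"] = start_post);
}

// Viterbi decoding in log space, restarting at run boundaries. Ties are
// broken toward the lower state index, deterministically. Returns a 1-based
// state path.
// [[Rcpp::export]]
IntegerVector viterbi_cpp(const NumericMatrix& logdens, const NumericVector& linit,
                          const NumericMatrix& ltrans, const IntegerVector& run_starts,
                          const IntegerVector& run_lengths) {
  const int T = logdens.nrow(), K = logdens.ncol(), R = run_starts.size();
  IntegerVector path(T);
  std::vector<double> delta((size_t)T * K);
  std::vector<int> psi((size_t)T * K);

  for (int r = 0; r < R; ++r) {
    const int s = run_starts[r] - 1, L = run_lengths[r];
    for (int k = 0; k < K; ++k) delta[(size_t)s * K + k] = linit[k] + logdens(s, k);
    for (int t = s + 1; t < s + L; ++t) {
      for (int k = 0; k < K; ++k) {
        double best = delta[(size_t)(t - 1) * K] + ltrans(0, k);
        int arg = 0;
        for (int j = 1; j < K; ++j) {
          double v = delta[(size_t)(t - 1) * K + j] + ltrans(j, k);
          if (v > best) { best = v; arg = j; } // strict >: lower index wins ties
        }
        delta[(size_t)t * K + k] = best + logdens(t, k);
        psi[(size_t)t * K + k] = arg;
      }
    }
    int last = s + L - 1, arg = 0;
    double best = delta[(size_t)last * K];
    for (int j = 1; j < K; ++j)
      if (delta[(size_t)last * K + j] > best) { best = delta[(size_t)last * K + j]; arg = j; }
    path[last] = arg + 1;
    for (int t = last; t > s; --t) {
      arg = psi[(size_t)t * K + arg];
      path[t - 1] = arg + 1;
    }
  }
  return path;
}
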
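#include <Rcpp.h>
using namespace Rcpp;

// Log-space forward recursion over a step series split into bursts.
// logdens: n x K matrix of per-observation log emission densities.
// log_trans: K x K log transition matrix (rows: from).
// log_init: length-K log initial distribution.
// new_burst: length-n logical; TRUE where a burst starts (alpha reset to init).
// Returns the total log-likelihood.
// [[Rcpp::export(rng = false)]]
double forward_loglik_cpp(const NumericMatrix& logdens,
                          const NumericMatrix& log_trans,
                          const NumericVector& log_init,
                          const LogicalVector& new_burst) {
  const int n = logdens.nrow(), K = logdens.ncol();
  std::vector<double> alpha(K), tmp(K);
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    if (new_burst[t]) {
      for (int k = 0; k < K; ++k) alpha[k] = log_init[k] + logdens(t, k);
    } else {
      for (int k = 0; k < K; ++k) {
        // logsumexp over previous states j of alpha[j] + log_trans(j, k)
        double m = R_NegInf;
        for (int j = 0; j < K; ++j) {
          double v = alpha[j] + log_trans(j, k);
          if (v > m) m = v;
        }
        double s = 0.0;
        if (R_finite(m)) {
          for (int j = 0; j < K; ++j) s += std::exp(alpha[j] + log_trans(j, k) - m);
          tmp[k] = m + std::log(s) + logdens(t, k);
        } else {
          tmp[k] = R_NegInf;
        }
      }
      alpha = tmp;
    }
    // rescale at burst ends to accumulate the likelihood burst by burst
    bool last = (t == n - 1) || new_burst[t + 1];
    if (last) {
      double m = R_NegInf;
      for (int k = 0; k < K; ++k) if (alpha[k] > m) m = alpha[k];
      if (!R_finite(m)) return R_NegInf;
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += std::exp(alpha[k] - m);
      ll += m + std::log(s);
    }
  }
  return ll;
}

// Viterbi decoding, one most-probable path per burst.
// Ties broken toward the lower state index (strict > comparison).
// Returns 1-based state indices, length n.
// [[Rcpp::export(rng = false)]]
IntegerVector viterbi_cpp(const NumericMatrix& logdens,
                          const NumericMatrix& log_trans,
                          const NumericVector& log_init,
                          const LogicalVector& new_burst) {
  const int n = logdens.nrow(), K = logdens.ncol();
  IntegerVector path(n);
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  for (int t = 0; t < n; ++t) {
    if (new_burst[t]) {
      for (int k = 0; k < K; ++k) {
        delta(t, k) = log_init[k] + logdens(t, k);
        psi(t, k) = -1;
      }
    } else {
      for (int k = 0; k < K; ++k) {
        double best = delta(t - 1, 0) + log_trans(0, k);
        int arg = 0;
        for (int j = 1; j < K; ++j) {
          double v = delta(t - 1, j) + log_trans(j, k);
          if (v > best) { best = v; arg = j; }
        }
        delta(t, k) = best + logdens(t, k);
        psi(t, k) = arg;
      }
    }
    bool last = (t == n - 1) || new_burst[t + 1];
    if (last) {
      // backtrack this burst
      double best = delta(t, 0);
      int arg = 0;
      for (int k = 1; k < K; ++k) if (delta(t, k) > best) { best = delta(t, k); arg = k; }
      int s = t;
      path[s] = arg + 1;
      while (psi(s, arg) >= 0) {
        arg = psi(s, arg);
        --s;
        path[s] = arg + 1;
      }
    }
  }
  return path;
}
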
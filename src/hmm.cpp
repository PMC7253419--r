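#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over independent sequences.
//
// logEmiss: n x K matrix of per-bin log emission likelihoods.
// trans:    K x K row-stochastic transition matrix.
// init:     length-K initial distribution.
// seqStart: 1-based start index of each independent sequence (chromosome).
// seqLen:   length of each sequence; sum(seqLen) == n.
//
// Returns gamma (n x K posteriors), xiSum (K x K expected transition
// counts), initGamma (summed first-bin posteriors) and logLik.
// [[Rcpp::export]]
List cpp_forward_backward(const NumericMatrix& logEmiss,
                          const NumericMatrix& trans,
                          const NumericVector& init,
                          const IntegerVector& seqStart,
                          const IntegerVector& seqLen) {
  const int n = logEmiss.nrow(), K = logEmiss.ncol(), S = seqStart.size();
  NumericMatrix gamma(n, K), xiSum(K, K);
  NumericVector initGamma(K);
  double logLik = 0.0;

  NumericMatrix alpha(n, K), beta(n, K), emis(n, K);
  NumericVector cscale(n), shift(n);

  // shift emissions to probability scale per bin (constant absorbed in logLik)
  for (int t = 0; t < n; ++t) {
    double m = logEmiss(t, 0);
    for (int k = 1; k < K; ++k) if (logEmiss(t, k) > m) m = logEmiss(t, k);
    shift[t] = m;
    for (int k = 0; k < K; ++k) emis(t, k) = std::exp(logEmiss(t, k) - m);
  }

  for (int s = 0; s < S; ++s) {
    const int a = seqStart[s] - 1, L = seqLen[s];
    // forward
    double c = 0.0;
    for (int k = 0; k < K; ++k) {
      alpha(a, k) = init[k] * emis(a, k);
      c += alpha(a, k);
    }
    cscale[a] = c;
    for (int k = 0; k < K; ++k) alpha(a, k) /= c;
    for (int t = a + 1; t < a + L; ++t) {
      c = 0.0;
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int j = 0; j < K; ++j) acc += alpha(t - 1, j) * trans(j, k);
        alpha(t, k) = acc * emis(t, k);
        c += alpha(t, k);
      }
      cscale[t] = c;
      for (int k = 0; k < K; ++k) alpha(t, k) /= c;
    }
    // backward
    for (int k = 0; k < K; ++k) beta(a + L - 1, k) = 1.0;
    for (int t = a + L - 2; t >= a; --t) {
      for (int j = 0; j < K; ++j) {
        double acc = 0.0;
        for (int k = 0; k < K; ++k)
          acc += trans(j, k) * emis(t + 1, k) * beta(t + 1, k);
        beta(t, j) = acc / cscale[t + 1];
      }
    }
    // posteriors, transition expectations, log-likelihood
    for (int t = a; t < a + L; ++t) {
      double tot = 0.0;
      for (int k = 0; k < K; ++k) tot += alpha(t, k) * beta(t, k);
      for (int k = 0; k < K; ++k) gamma(t, k) = alpha(t, k) * beta(t, k) / tot;
      logLik += std::log(cscale[t]) + shift[t];
    }
    for (int k = 0; k < K; ++k) initGamma[k] += gamma(a, k);
    for (int t = a; t < a + L - 1; ++t) {
      double tot = 0.0;
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          tot += alpha(t, j) * trans(j, k) * emis(t + 1, k) * beta(t + 1, k);
      for (int j = 0; j < K; ++j)
        for (int k = 0; k < K; ++k)
          xiSum(j, k) += alpha(t, j) * trans(j, k) * emis(t + 1, k) *
                         beta(t + 1, k) / tot;
    }
  }
  return List::create(_["gamma"] = gamma, _["xiSum"] = xiSum,
                      _["initGamma"] = initGamma, _["logLik"] = logLik);
}

// Viterbi decoding over independent sequences; ties go to the lower state id.
// [[Rcpp::export]]
IntegerVector cpp_viterbi(const NumericMatrix& logEmiss,
                          const NumericMatrix& trans,
                          const NumericVector& init,
                          const IntegerVector& seqStart,
                          const IntegerVector& seqLen) {
  const int n = logEmiss.nrow(), K = logEmiss.ncol(), S = seqStart.size();
  IntegerVector path(n);
  NumericMatrix delta(n, K);
  IntegerMatrix psi(n, K);
  NumericMatrix ltrans(K, K);
  NumericVector linit(K);
  for (int j = 0; j < K; ++j) {
    linit[j] = std::log(init[j]);
    for (int k = 0; k < K; ++k) ltrans(j, k) = std::log(trans(j, k));
  }
  for (int s = 0; s < S; ++s) {
    const int a = seqStart[s] - 1, L = seqLen[s];
    for (int k = 0; k < K; ++k) delta(a, k) = linit[k] + logEmiss(a, k);
    for (int t = a + 1; t < a + L; ++t) {
      for (int k = 0; k < K; ++k) {
        double best = delta(t - 1, 0) + ltrans(0, k);
        int arg = 0;
        for (int j = 1; j < K; ++j) {
          double v = delta(t - 1, j) + ltrans(j, k);
          if (v > best) { best = v; arg = j; }
        }
        delta(t, k) = best + logEmiss(t, k);
        psi(t, k) = arg;
      }
    }
    int last = a + L - 1, arg = 0;
    for (int k = 1; k < K; ++k) if (delta(last, k) > delta(last, arg)) arg = k;
    path[last] = arg + 1;
    for (int t = last; t > a; --t) {
      arg = psi(t, arg);
      path[t - 1] = arg + 1;
    }
  }
  return path;
}
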
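#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward pass. obs is 1-based symbol index into emission columns.
// Returns log P(obs | params).
// [[Rcpp::export(name = ".hmm_forward_cpp")]]
double hmm_forward_cpp(IntegerVector obs, NumericMatrix trans,
                       NumericMatrix emis, NumericVector init) {
  const int K = trans.nrow(), T = obs.size();
  std::vector<double> alpha(K), tmp(K);
  double loglik = 0.0;
  for (int i = 0; i < K; ++i) alpha[i] = init[i] * emis(i, obs[0] - 1);
  double c = std::accumulate(alpha.begin(), alpha.end(), 0.0);
  if (c <= 0) return R_NegInf;
  for (int i = 0; i < K; ++i) alpha[i] /= c;
  loglik += std::log(c);
  for (int t = 1; t < T; ++t) {
    const int o = obs[t] - 1;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha[i] * trans(i, j);
      tmp[j] = s * emis(j, o);
    }
    c = std::accumulate(tmp.begin(), tmp.end(), 0.0);
    if (c <= 0) return R_NegInf;
    for (int j = 0; j < K; ++j) alpha[j] = tmp[j] / c;
    loglik += std::log(c);
  }
  return loglik;
}

// Forward-backward: returns posterior state probabilities (T x K),
// expected transition counts (K x K) and the log-likelihood.
// [[Rcpp::export(name = ".hmm_fwbw_cpp")]]
List hmm_fwbw_cpp(IntegerVector obs, NumericMatrix trans,
                  NumericMatrix emis, NumericVector init) {
  const int K = trans.nrow(), T = obs.size();
  NumericMatrix alpha(T, K), beta(T, K), gamma(T, K), xi(K, K);
  std::vector<double> scale(T);
  double loglik = 0.0;
  for (int i = 0; i < K; ++i) alpha(0, i) = init[i] * emis(i, obs[0] - 1);
  double c = 0; for (int i = 0; i < K; ++i) c += alpha(0, i);
  scale[0] = c; loglik += std::log(c);
  for (int i = 0; i < K; ++i) alpha(0, i) /= c;
  for (int t = 1; t < T; ++t) {
    const int o = obs[t] - 1;
    c = 0;
    for (int j = 0; j < K; ++j) {
      double s = 0.0;
      for (int i = 0; i < K; ++i) s += alpha(t - 1, i) * trans(i, j);
      alpha(t, j) = s * emis(j, o);
      c += alpha(t, j);
    }
    scale[t] = c; loglik += std::log(c);
    for (int j = 0; j < K; ++j) alpha(t, j) /= c;
  }
  for (int i = 0; i < K; ++i) beta(T - 1, i) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    const int o = obs[t + 1] - 1;
    for (int i = 0; i < K; ++i) {
      double s = 0.0;
      for (int j = 0; j < K; ++j) s += trans(i, j) * emis(j, o) * beta(t + 1, j);
      beta(t, i) = s / scale[t + 1];
    }
  }
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int i = 0; i < K; ++i) { gamma(t, i) = alpha(t, i) * beta(t, i); s += gamma(t, i); }
    for (int i = 0; i < K; ++i) gamma(t, i) /= s;
  }
  for (int t = 0; t < T - 1; ++t) {
    const int o = obs[t + 1] - 1;
    for (int i = 0; i < K; ++i)
      for (int j = 0; j < K; ++j)
        xi(i, j) += alpha(t, i) * trans(i, j) * emis(j, o) * beta(t + 1, j) / scale[t + 1];
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = loglik);
}

// Viterbi in log space; ties broken toward the lower state index.
// [[Rcpp::export(name = ".hmm_viterbi_cpp")]]
List hmm_viterbi_cpp(IntegerVector obs, NumericMatrix trans,
                     NumericMatrix emis, NumericVector init) {
  const int K = trans.nrow(), T = obs.size();
  NumericMatrix delta(T, K);
  IntegerMatrix psi(T, K);
  auto lg = [](double x) { return x > 0 ? std::log(x) : R_NegInf; };
  for (int i = 0; i < K; ++i) delta(0, i) = lg(init[i]) + lg(emis(i, obs[0] - 1));
  for (int t = 1; t < T; ++t) {
    const int o = obs[t] - 1;
    for (int j = 0; j < K; ++j) {
      double best = R_NegInf; int arg = 0;
      for (int i = 0; i < K; ++i) {
        const double v = delta(t - 1, i) + lg(trans(i, j));
        if (v > best) { best = v; arg = i; }   // strict: ties keep lower i
      }
      delta(t, j) = best + lg(emis(j, o));
      psi(t, j) = arg;
    }
  }
  IntegerVector path(T);
  double best = R_NegInf; int arg = 0;
  for (int i = 0; i < K; ++i)
    if (delta(T - 1, i) > best) { best = delta(T - 1, i); arg = i; }
  path[T - 1] = arg;
  for (int t = T - 2; t >= 0; --t) path[t] = psi(t + 1, path[t + 1]);
  return List::create(_["path"] = path, _["logprob"] = best);
}

// Baum-Welch with emission-only learning: the transition M-step is
// dominated by pseudocounts anchored to the fixed matrix, so transitions
// stay within ~1e-6 of their fixed values; the initial distribution is
// held fixed. Emission rows are floored and renormalized each M-step.
// [[Rcpp::export(name = ".hmm_baum_welch_cpp")]]
List hmm_baum_welch_cpp(IntegerVector obs, NumericMatrix trans_fixed,
                        NumericMatrix emis_init, NumericVector init,
                        double pseudocount, double tol, int max_iter,
                        double emis_floor) {
  const int K = trans_fixed.nrow(), M = emis_init.ncol(), T = obs.size();
  NumericMatrix trans = clone(trans_fixed);
  NumericMatrix emis = clone(emis_init);
  std::vector<double> trace;
  double prev = R_NegInf;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    List fb = hmm_fwbw_cpp(obs, trans, emis, init);
    NumericMatrix gamma = fb["gamma"];
    NumericMatrix xi = fb["xi"];
    double ll = fb["loglik"];
    trace.push_back(ll);
    if (it > 1 && ll - prev < tol) { prev = ll; break; }
    prev = ll;
    // transition M-step with huge pseudocounts anchored to the fixed matrix
    for (int i = 0; i < K; ++i) {
      double row = 0.0;
      for (int j = 0; j < K; ++j) row += xi(i, j) + pseudocount * trans_fixed(i, j);
      for (int j = 0; j < K; ++j)
        trans(i, j) = (xi(i, j) + pseudocount * trans_fixed(i, j)) / row;
    }
    // emission M-step
    for (int i = 0; i < K; ++i) {
      std::vector<double> num(M, 0.0);
      for (int t = 0; t < T; ++t) num[obs[t] - 1] += gamma(t, i);
      double row = std::accumulate(num.begin(), num.end(), 0.0);
      double row2 = 0.0;
      for (int m = 0; m < M; ++m) { num[m] = std::max(num[m] / row, emis_floor); row2 += num[m]; }
      for (int m = 0; m < M; ++m) emis(i, m) = num[m] / row2;
    }
  }
  return List::create(_["emission"] = emis, _["transition"] = trans,
                      _["loglik"] = prev,
                      _["loglik_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["iterations"] = (int)trace.size());
}
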
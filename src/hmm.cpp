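#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward over the diploid ancestry-pair state space.
//
// The step-j transition matrix is assembled on the fly from the identity
// and two constant matrices: T(r) = (1-r)^2 I + r(1-r) B + r^2 C, where B
// and C collect the single- and double-recombination mass of the
// independent-haplotype product construction collapsed to unordered pairs.
// Scaling (per-step normalization) keeps the recursion in linear space
// without underflow for sequences of 1e5+ observations; the log-likelihood
// is the sum of log scale factors.
//
// pi: initial distribution over states (length S), emitted at the first
//     observation (the start state is silent).
// B, C: S x S constant transition components.
// r: recombination probabilities between consecutive observations
//    (length L-1).
// eobs: S x L matrix, eobs(s, j) = emission probability of observation j
//       from state s.
// [[Rcpp::export(name = ".fb_decode")]]
List fb_decode(NumericVector pi, NumericMatrix B, NumericMatrix C,
               NumericVector r, NumericMatrix eobs) {
  const int S = pi.size();
  const int L = eobs.ncol();
  NumericMatrix alpha(L, S), beta(L, S), gamma(L, S);
  NumericVector scale(L);
  std::vector<double> T(S * S);

  auto build_T = [&](double rj) {
    const double c0 = (1.0 - rj) * (1.0 - rj);
    const double c1 = rj * (1.0 - rj);
    const double c2 = rj * rj;
    for (int a = 0; a < S; ++a)
      for (int b = 0; b < S; ++b)
        T[a * S + b] = c1 * B(a, b) + c2 * C(a, b) + (a == b ? c0 : 0.0);
  };

  double loglik = 0.0;
  // forward
  double s0 = 0.0;
  for (int s = 0; s < S; ++s) {
    alpha(0, s) = pi[s] * eobs(s, 0);
    s0 += alpha(0, s);
  }
  if (s0 <= 0.0) stop("zero forward mass at observation 1");
  scale[0] = s0;
  for (int s = 0; s < S; ++s) alpha(0, s) /= s0;
  loglik += std::log(s0);

  for (int j = 1; j < L; ++j) {
    build_T(r[j - 1]);
    double sj = 0.0;
    for (int s = 0; s < S; ++s) {
      double acc = 0.0;
      for (int a = 0; a < S; ++a) acc += alpha(j - 1, a) * T[a * S + s];
      double v = acc * eobs(s, j);
      alpha(j, s) = v;
      sj += v;
    }
    if (sj <= 0.0) stop("zero forward mass at observation %d", j + 1);
    scale[j] = sj;
    for (int s = 0; s < S; ++s) alpha(j, s) /= sj;
    loglik += std::log(sj);
  }

  // backward
  for (int s = 0; s < S; ++s) beta(L - 1, s) = 1.0;
  for (int j = L - 2; j >= 0; --j) {
    build_T(r[j]);
    for (int a = 0; a < S; ++a) {
      double acc = 0.0;
      for (int b = 0; b < S; ++b)
        acc += T[a * S + b] * eobs(b, j + 1) * beta(j + 1, b);
      beta(j, a) = acc / scale[j + 1];
    }
  }

  for (int j = 0; j < L; ++j) {
    double z = 0.0;
    for (int s = 0; s < S; ++s) {
      gamma(j, s) = alpha(j, s) * beta(j, s);
      z += gamma(j, s);
    }
    for (int s = 0; s < S; ++s) gamma(j, s) /= z;
  }

  return List::create(_["gamma"] = gamma, _["loglik"] = loglik);
}
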
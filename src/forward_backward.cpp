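#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward recursion for a hidden Markov chain with
// time-varying transition matrices.
//
// logB: T x Z emission log-likelihoods.
// A:    Z x Z x T array; A(i, j, t) = P(z_t = j | z_{t-1} = i). The t = 0
//       slice is unused.
// pi:   initial state distribution.
//
// Returns gamma (T x Z state marginals), xi ((T-1) x Z*Z pairwise
// posteriors, column-major over (i, j)), and the marginal log-likelihood.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(NumericMatrix logB, NumericVector A, NumericVector pi) {
  const int T = logB.nrow();
  const int Z = logB.ncol();
  IntegerVector dims = A.attr("dim");
  if (dims[0] != Z || dims[1] != Z || dims[2] != T)
    stop("transition array dimensions do not match emissions");

  NumericMatrix b(T, Z);      // scaled emission likelihoods
  NumericVector mrow(T);
  for (int t = 0; t < T; ++t) {
    double m = logB(t, 0);
    for (int z = 1; z < Z; ++z) if (logB(t, z) > m) m = logB(t, z);
    mrow[t] = m;
    for (int z = 0; z < Z; ++z) b(t, z) = std::exp(logB(t, z) - m);
  }

  auto Aat = [&](int i, int j, int t) -> double {
    return A[i + Z * (j + Z * t)];
  };

  NumericMatrix alpha(T, Z), beta(T, Z);
  double loglik = 0.0;

  // forward
  double c = 0.0;
  for (int z = 0; z < Z; ++z) { alpha(0, z) = pi[z] * b(0, z); c += alpha(0, z); }
  if (c <= 0) stop("forward pass underflow at the first step");
  for (int z = 0; z < Z; ++z) alpha(0, z) /= c;
  loglik += std::log(c) + mrow[0];
  for (int t = 1; t < T; ++t) {
    c = 0.0;
    for (int j = 0; j < Z; ++j) {
      double s = 0.0;
      for (int i = 0; i < Z; ++i) s += alpha(t - 1, i) * Aat(i, j, t);
      alpha(t, j) = s * b(t, j);
      c += alpha(t, j);
    }
    if (c <= 0) stop("forward pass underflow");
    for (int j = 0; j < Z; ++j) alpha(t, j) /= c;
    loglik += std::log(c) + mrow[t];
  }

  // backward (rescaled each step; any per-step scale cancels in gamma/xi)
  for (int z = 0; z < Z; ++z) beta(T - 1, z) = 1.0;
  for (int t = T - 2; t >= 0; --t) {
    double s = 0.0;
    for (int i = 0; i < Z; ++i) {
      double v = 0.0;
      for (int j = 0; j < Z; ++j)
        v += Aat(i, j, t + 1) * b(t + 1, j) * beta(t + 1, j);
      beta(t, i) = v;
      s += v;
    }
    if (s <= 0) stop("backward pass underflow");
    for (int i = 0; i < Z; ++i) beta(t, i) /= s;
  }

  NumericMatrix gamma(T, Z);
  for (int t = 0; t < T; ++t) {
    double s = 0.0;
    for (int z = 0; z < Z; ++z) { gamma(t, z) = alpha(t, z) * beta(t, z); s += gamma(t, z); }
    for (int z = 0; z < Z; ++z) gamma(t, z) /= s;
  }

  NumericMatrix xi(T > 1 ? T - 1 : 0, Z * Z);
  for (int t = 1; t < T; ++t) {
    double s = 0.0;
    for (int j = 0; j < Z; ++j)
      for (int i = 0; i < Z; ++i) {
        double v = alpha(t - 1, i) * Aat(i, j, t) * b(t, j) * beta(t, j);
        xi(t - 1, i + Z * j) = v;
        s += v;
      }
    for (int k = 0; k < Z * Z; ++k) xi(t - 1, k) /= s;
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi,
                      _["loglik"] = loglik);
}
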
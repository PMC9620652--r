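#include <Rcpp.h>
using namespace Rcpp;

// Multinomial EM refit of signature exposures.
//
// For a spectrum x (96 counts) and fixed column-stochastic signature matrix
// P (96 x K), maximise the multinomial log-likelihood
//   L(e) = sum_c x_c * log(sum_k e_k * P_ck)
// over the K-simplex. Multiplicative EM update from uniform initialisation:
//   e_k <- e_k * sum_c x_c * P_ck / m_c / n,   m = P e,  n = sum x.
// The update is monotone in L and keeps the iterates strictly inside the
// simplex, so results are deterministic and tie-free. Convergence: max
// absolute exposure change < tol, or max_iter.
//
// Spectra are fit in batch (columns of X) because FDR calibration refits
// hundreds of thousands of simulated spectra.

// [[Rcpp::export(name = ".em_fit_batch")]]
List em_fit_batch(NumericMatrix X, NumericMatrix P,
                  int max_iter, double tol) {
  const int C = P.nrow(), K = P.ncol(), M = X.ncol();
  if (X.nrow() != C) stop("spectrum/catalog channel mismatch");
  NumericMatrix expo(K, M);
  NumericVector loglik(M);
  IntegerVector iters(M);
  std::vector<double> e(K), enew(K), m(C);
  for (int s = 0; s < M; ++s) {
    double n = 0.0;
    for (int c = 0; c < C; ++c) n += X(c, s);
    if (n <= 0.0) {
      for (int k = 0; k < K; ++k) expo(k, s) = NA_REAL;
      loglik[s] = NA_REAL;
      continue;
    }
    for (int k = 0; k < K; ++k) e[k] = 1.0 / K;
    int it = 0;
    for (; it < max_iter; ++it) {
      for (int c = 0; c < C; ++c) {
        double acc = 0.0;
        for (int k = 0; k < K; ++k) acc += e[k] * P(c, k);
        m[c] = acc;
      }
      double delta = 0.0;
      for (int k = 0; k < K; ++k) {
        double acc = 0.0;
        for (int c = 0; c < C; ++c) {
          double x = X(c, s);
          if (x > 0.0 && m[c] > 0.0) acc += x * P(c, k) / m[c];
        }
        enew[k] = e[k] * acc / n;
        double d = std::fabs(enew[k] - e[k]);
        if (d > delta) delta = d;
      }
      // renormalise against drift when some counts fall on zero-mass channels
      double tot = 0.0;
      for (int k = 0; k < K; ++k) tot += enew[k];
      if (tot > 0.0) for (int k = 0; k < K; ++k) enew[k] /= tot;
      e = enew;
      if (delta < tol) { ++it; break; }
    }
    double ll = 0.0;
    for (int c = 0; c < C; ++c) {
      double x = X(c, s);
      if (x > 0.0) {
        double acc = 0.0;
        for (int k = 0; k < K; ++k) acc += e[k] * P(c, k);
        ll += (acc > 0.0) ? x * std::log(acc) : R_NegInf;
      }
    }
    for (int k = 0; k < K; ++k) expo(k, s) = e[k];
    loglik[s] = ll;
    iters[s] = it;
  }
  return List::create(_["exposures"] = expo, _["loglik"] = loglik,
                      _["iterations"] = iters);
}
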
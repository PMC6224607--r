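#include <Rcpp.h>
using namespace Rcpp;

// Transient solution of a finite CTMC by uniformization:
//   p(t)' = p0' * exp(Qt) = sum_k dpois(k; Lambda*t) * p0' * P^k,
//   P = I + Q / Lambda, Lambda >= max_i |Q_ii|.
// The caller passes P TRANSPOSED in compressed sparse column form
// (slots of a dgCMatrix), so each step is v <- Pt %*% v.
// All requested times are accumulated in a single pass over k.

// [[Rcpp::export]]
NumericMatrix ctmc_uniformize_cpp(IntegerVector Pp, IntegerVector Pi,
                                  NumericVector Px, int n,
                                  double Lambda, NumericVector times,
                                  NumericVector p0, double tol) {
  int n_t = times.size();
  NumericMatrix out(n, n_t);
  if (Lambda <= 0.0) {           // no events at all: p(t) = p0
    for (int j = 0; j < n_t; ++j)
      for (int i = 0; i < n; ++i) out(i, j) = p0[i];
    return out;
  }
  double t_max = 0.0;
  for (int j = 0; j < n_t; ++j) if (times[j] > t_max) t_max = times[j];
  // number of uniformization terms: Poisson upper tail below tol at t_max
  int K = (int) R::qpois(1.0 - tol, Lambda * t_max, 1, 0) + 5;

  std::vector<double> v(p0.begin(), p0.end()), w(n);
  for (int k = 0; k <= K; ++k) {
    for (int j = 0; j < n_t; ++j) {
      double wt = R::dpois((double) k, Lambda * times[j], 0);
      if (wt > 0.0) {
        for (int i = 0; i < n; ++i) out(i, j) += wt * v[i];
      }
    }
    if (k == K) break;
    // w <- Pt %*% v  (CSC: column c of Pt scatters v[c])
    std::fill(w.begin(), w.end(), 0.0);
    for (int c = 0; c < n; ++c) {
      double vc = v[c];
      if (vc == 0.0) continue;
      for (int idx = Pp[c]; idx < Pp[c + 1]; ++idx)
        w[Pi[idx]] += Px[idx] * vc;
    }
    v.swap(w);
  }
  return out;
}
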
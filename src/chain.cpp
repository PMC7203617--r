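#include <Rcpp.h>
using namespace Rcpp;

// Simulate a discrete Markov chain with k states.
// P is k x k row-stochastic; init is a length-k probability vector for the
// first state. Uses R's RNG so results are governed by set.seed().
// [[Rcpp::export(name = ".sim_markov_chain")]]
IntegerVector sim_markov_chain(int n, NumericMatrix P, NumericVector init) {
  int k = P.nrow();
  IntegerVector out(n);
  if (n == 0) return out;

  // cumulative rows
  NumericMatrix C(k, k);
  for (int i = 0; i < k; ++i) {
    double acc = 0.0;
    for (int j = 0; j < k; ++j) {
      acc += P(i, j);
      C(i, j) = acc;
    }
  }
  NumericVector ci(k);
  double acc = 0.0;
  for (int j = 0; j < k; ++j) { acc += init[j]; ci[j] = acc; }

  double u = unif_rand();
  int s = 0;
  while (s < k - 1 && u > ci[s]) ++s;
  out[0] = s + 1;
  for (int t = 1; t < n; ++t) {
    u = unif_rand();
    int j = 0;
    while (j < k - 1 && u > C(s, j)) ++j;
    s = j;
    out[t] = s + 1;
  }
  return out;
}
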
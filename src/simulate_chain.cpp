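#include <Rcpp.h>
using namespace Rcpp;

// Sample Markov chain realisations from a row-cumulative transition matrix.
// cumP: n_states x n_states matrix of row-wise cumulative probabilities.
// init: 1-based initial state per trajectory.
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix simulate_chain_cpp(NumericMatrix cumP, IntegerVector init,
                                 int n_steps) {
  const int n_traj = init.size();
  const int n_states = cumP.nrow();
  IntegerMatrix out(n_steps, n_traj);
  RNGScope scope;
  for (int tr = 0; tr < n_traj; ++tr) {
    int s = init[tr] - 1;
    out(0, tr) = s + 1;
    for (int t = 1; t < n_steps; ++t) {
      double u = unif_rand();
      // binary search for first cumP(s, k) >= u
      int lo = 0, hi = n_states - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (cumP(s, mid) >= u) hi = mid; else lo = mid + 1;
      }
      s = lo;
      out(t, tr) = s + 1;
    }
  }
  return out;
}
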
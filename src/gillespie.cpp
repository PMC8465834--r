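#include <Rcpp.h>
using namespace Rcpp;

// Jump-chain simulation of the absorbing kinetic scheme. Terminal yields of
// a CTMC depend only on the embedded jump chain, so exponential waiting
// times are not sampled. Uses R's RNG (unif_rand) so set.seed() governs
// reproducibility.
//
// Q: generator, column convention (Q[j,i] = rate i -> j, j != i).
// absorbing: 1-based indices of absorbing states.
// Returns counts per absorbing state, the number of walkers abandoned at
// max_jumps, and the total number of jumps taken.
// [[Rcpp::export(name = "gillespie_absorb")]]
NumericVector gillespie_absorb(NumericMatrix Q, IntegerVector absorbing,
                               int init, int n_walkers, double max_jumps) {
  const int n = Q.nrow();
  std::vector<bool> is_abs(n, false);
  for (int k = 0; k < absorbing.size(); ++k) is_abs[absorbing[k] - 1] = true;

  // Per source state: cumulative transition probabilities and targets.
  std::vector< std::vector<double> > cum(n);
  std::vector< std::vector<int> > tgt(n);
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int j = 0; j < n; ++j)
      if (j != i && Q(j, i) > 0.0) tot += Q(j, i);
    if (tot <= 0.0) continue;
    double acc = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j != i && Q(j, i) > 0.0) {
        acc += Q(j, i) / tot;
        cum[i].push_back(acc);
        tgt[i].push_back(j);
      }
    }
    cum[i].back() = 1.0;  // guard against rounding
  }

  std::vector<double> abs_counts(n, 0.0);
  double capped = 0.0, jumps_total = 0.0;
  RNGScope scope;
  for (int w = 0; w < n_walkers; ++w) {
    int s = init - 1;
    double jumps = 0.0;
    while (!is_abs[s]) {
      if (cum[s].empty() || jumps >= max_jumps) { s = -1; break; }
      double u = unif_rand();
      size_t lo = std::lower_bound(cum[s].begin(), cum[s].end(), u) -
                  cum[s].begin();
      s = tgt[s][lo];
      jumps += 1.0;
    }
    jumps_total += jumps;
    if (s < 0) capped += 1.0; else abs_counts[s] += 1.0;
    if (w % 4096 == 0) checkUserInterrupt();
  }

  NumericVector out(absorbing.size() + 2);
  for (int k = 0; k < absorbing.size(); ++k)
    out[k] = abs_counts[absorbing[k] - 1];
  out[absorbing.size()] = capped;
  out[absorbing.size() + 1] = jumps_total;
  return out;
}
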
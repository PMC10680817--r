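#include <Rcpp.h>
using namespace Rcpp;

// Single-spin-flip Metropolis dynamics for an Ising system on an explicit
// undirected graph, log-weight J_edge * sum_{(i,j) in E} s_i s_j.
//
// adj_ptr / adj_idx: CSR adjacency (0-based); adj_ptr has n_nodes + 1
// entries. Each recorded step performs flips_per_step single-spin attempts
// at uniformly random nodes; synchrony (mean spin) is recorded after the
// attempts of each step. Uses R's RNG so set.seed() governs the run.
//
// [[Rcpp::export]]
NumericVector metropolis_core(IntegerVector adj_ptr, IntegerVector adj_idx,
                              double j_edge, IntegerVector init_spins,
                              int n_steps, int flips_per_step, int burn_in) {
  const int n = init_spins.size();
  std::vector<int> spin(init_spins.begin(), init_spins.end());
  long sum_spin = 0;
  for (int i = 0; i < n; ++i) sum_spin += spin[i];

  NumericVector out(n_steps);
  const int total = burn_in + n_steps;
  for (int step = 0; step < total; ++step) {
    for (int a = 0; a < flips_per_step; ++a) {
      int i = (int)(unif_rand() * n);
      if (i == n) i = n - 1;  // guard against unif_rand() == 1.0
      long h = 0;
      for (int k = adj_ptr[i]; k < adj_ptr[i + 1]; ++k) h += spin[adj_idx[k]];
      // flipping spin i changes the log-weight by -2 J s_i h_i
      double dlogw = -2.0 * j_edge * spin[i] * (double)h;
      if (dlogw >= 0.0 || unif_rand() < std::exp(dlogw)) {
        spin[i] = -spin[i];
        sum_spin += 2 * spin[i];
      }
    }
    if (step >= burn_in) out[step - burn_in] = (double)sum_spin / n;
  }
  return out;
}
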
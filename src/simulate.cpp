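#include <Rcpp.h>
using namespace Rcpp;

// Synchronous update of N probabilistic binary neurons.
//
// Connectivity is passed in compressed sparse column form (p, idx, x), so
// column j holds the outgoing weights of neuron j: x[k] is the weight of
// the connection j -> idx[k].  Per step the input to neuron i is
// eta + sum_j W[i,j] s_j(t-1); the firing probability is that input clamped
// to [0,1]; states are drawn with R's RNG so runs are reproducible under
// set.seed().
//
// Only active (s=1) presynaptic neurons contribute, so cost per step is
// proportional to the number of nonzeros in active columns.  Group sums of
// the state vector are accumulated after the burn-in; the full raster is
// stored only on request (keep_states) since it is O(N*T).
//
// [[Rcpp::export]]
List sim_binary_net(IntegerVector p, IntegerVector idx, NumericVector x,
                    int n_neurons, double eta, int steps, int burn_in,
                    IntegerVector group, bool keep_states) {
  int ng = 0;
  for (int i = 0; i < n_neurons; ++i)
    if (group[i] + 1 > ng) ng = group[i] + 1;

  NumericMatrix group_sums(ng, steps);
  IntegerMatrix states;
  if (keep_states) states = IntegerMatrix(n_neurons, steps);

  std::vector<int> active, nxt;
  std::vector<double> input(n_neurons);
  active.reserve(n_neurons);
  nxt.reserve(n_neurons);

  for (int t = 0; t < burn_in + steps; ++t) {
    std::fill(input.begin(), input.end(), eta);
    for (size_t a = 0; a < active.size(); ++a) {
      int j = active[a];
      for (int k = p[j]; k < p[j + 1]; ++k) input[idx[k]] += x[k];
    }
    nxt.clear();
    for (int i = 0; i < n_neurons; ++i) {
      double pi = input[i];
      if (pi > 1.0) pi = 1.0;
      if (pi > 0.0 && unif_rand() < pi) nxt.push_back(i);
    }
    active.swap(nxt);
    if (t >= burn_in) {
      int tt = t - burn_in;
      for (size_t a = 0; a < active.size(); ++a) {
        group_sums(group[active[a]], tt) += 1.0;
        if (keep_states) states(active[a], tt) = 1;
      }
    }
  }

  if (keep_states)
    return List::create(_["group_sums"] = group_sums, _["states"] = states);
  return List::create(_["group_sums"] = group_sums);
}
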
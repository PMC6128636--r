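#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Izhikevich two-variable quadratic integrate-and-reset network on a 1 ms
// event grid with two 0.5 ms membrane substeps (the model's reference
// scheme). Synapses are impulses: a presynaptic spike adds its weight to the
// postsynaptic input current at the arrival step (delay quantized to 1 ms).
// Excitatory weights evolve under an additive nearest-neighbour pair STDP
// rule (tau = 20 ms), clipped to [0, w_max]; inhibitory weights are fixed.
// One uniformly chosen neuron per 1 ms step receives a stimulation current
// drawn from its type's normal distribution. Uses R's RNG, so runs are
// reproducible under set.seed().
// [[Rcpp::export]]
List sim_izhikevich_cpp(IntegerVector type,            // 0 = excitatory, 1 = inhibitory
                        IntegerVector syn_src, IntegerVector syn_tgt,
                        NumericVector syn_w, IntegerVector syn_delay,
                        int duration_ms,
                        double stim_mean_exc, double stim_sd_exc,
                        double stim_mean_inh, double stim_sd_inh,
                        bool stim_on, int stim_pulse_ms, NumericVector i_const,
                        NumericVector a, NumericVector b,
                        NumericVector c, NumericVector d,
                        bool stdp_on, double a_plus, double a_minus,
                        double tau, double w_max, double v_init_sd) {
  const int n = type.size();
  const int ns = syn_src.size();
  const int DMAX = 21;

  // CSR by source for propagation (syn_src/syn_tgt are 0-based)
  std::vector<int> out_off(n + 1, 0);
  for (int s = 0; s < ns; ++s) out_off[syn_src[s] + 1]++;
  for (int i = 0; i < n; ++i) out_off[i + 1] += out_off[i];
  std::vector<int> out_idx(ns);
  { std::vector<int> cur(out_off.begin(), out_off.end() - 1);
    for (int s = 0; s < ns; ++s) out_idx[cur[syn_src[s]]++] = s; }

  // excitatory afferent synapse lists by target (for potentiation)
  std::vector<std::vector<int> > aff_exc(n);
  for (int s = 0; s < ns; ++s)
    if (type[syn_src[s]] == 0) aff_exc[syn_tgt[s]].push_back(s);

  std::vector<double> w(syn_w.begin(), syn_w.end());
  std::vector<double> v(n), u(n), I(n, 0.0);
  for (int i = 0; i < n; ++i) {
    v[i] = -65.0;
    if (v_init_sd > 0) v[i] += v_init_sd * norm_rand();
    u[i] = b[i] * v[i];
  }

  std::vector<double> stim_I(n, 0.0);
  std::vector<int> stim_until(n, -1);
  std::vector<double> last_spike(n, -1e12);
  std::vector<double> last_arr(ns, -1e12);
  std::vector<std::vector<int> > ring(DMAX);
  std::vector<int> fired; fired.reserve(n);
  std::vector<int> sp_neuron; std::vector<int> sp_time;

  for (int t = 0; t < duration_ms; ++t) {
    std::fill(I.begin(), I.end(), 0.0);
    // deliver scheduled presynaptic arrivals
    std::vector<int>& slot = ring[t % DMAX];
    for (size_t q = 0; q < slot.size(); ++q) {
      int s = slot[q];
      int j = syn_tgt[s];
      I[j] += w[s];
      if (stdp_on && type[syn_src[s]] == 0) {
        // pre after post: depress
        double dt = (double)t - last_spike[j];
        if (dt >= 0 && dt < 7.0 * tau) {
          w[s] -= a_minus * std::exp(-dt / tau);
          if (w[s] < 0) w[s] = 0;
        }
        last_arr[s] = (double)t;
      }
    }
    slot.clear();
    // stochastic stimulation: one neuron per 1 ms step receives a current
    // pulse lasting stim_pulse_ms (amplitudes sit in the sustained-current
    // tonic-firing range of the neuron models, so the pulse outlives the step)
    if (stim_on) {
      int idx = (int)(unif_rand() * n);
      if (idx >= n) idx = n - 1;
      double amp = (type[idx] == 0)
        ? stim_mean_exc + stim_sd_exc * norm_rand()
        : stim_mean_inh + stim_sd_inh * norm_rand();
      stim_I[idx] = amp;
      stim_until[idx] = t + stim_pulse_ms;
    }
    for (int i = 0; i < n; ++i)
      if (t < stim_until[i]) I[i] += stim_I[i];
    // membrane update: two 0.5 ms substeps for v, one step for u
    fired.clear();
    for (int i = 0; i < n; ++i) {
      double Ii = I[i] + i_const[i];
      double vi = v[i], ui = u[i];
      vi += 0.5 * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + Ii);
      vi += 0.5 * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + Ii);
      ui += a[i] * (b[i] * vi - ui);
      if (!std::isfinite(vi))
        stop("membrane potential non-finite at step %d (neuron %d)", t, i + 1);
      if (vi >= 30.0) {
        sp_neuron.push_back(i + 1);
        sp_time.push_back(t);
        vi = c[i];
        ui += d[i];
        fired.push_back(i);
        last_spike[i] = (double)t;
      }
      v[i] = vi; u[i] = ui;
    }
    // propagate spikes and potentiate afferents of fired neurons
    for (size_t f = 0; f < fired.size(); ++f) {
      int i = fired[f];
      for (int q = out_off[i]; q < out_off[i + 1]; ++q) {
        int s = out_idx[q];
        ring[(t + syn_delay[s]) % DMAX].push_back(s);
      }
      if (stdp_on) {
        const std::vector<int>& aff = aff_exc[i];
        for (size_t q = 0; q < aff.size(); ++q) {
          int s = aff[q];
          double dt = (double)t - last_arr[s];
          if (dt >= 0 && dt < 7.0 * tau) {
            w[s] += a_plus * std::exp(-dt / tau);
            if (w[s] > w_max) w[s] = w_max;
          }
        }
      }
    }
  }
  return List::create(_["spike_neuron"] = IntegerVector(sp_neuron.begin(), sp_neuron.end()),
                      _["spike_time_ms"] = IntegerVector(sp_time.begin(), sp_time.end()),
                      _["weights"] = NumericVector(w.begin(), w.end()));
}
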
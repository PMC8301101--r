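#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Clock-driven forward-Euler simulation of one protocol phase.
//
// Neurons are indexed 0..n-1 with the n_exc excitatory neurons first.
// Synapses arrive as parallel edge arrays (0-based pre/post) split by class:
//   EE (plastic, normalized), EI (E->I, fixed), IE (I->E, fixed).
// External input events are (time, group) pairs; each event delivers one
// spike through a fixed input_w conductance to every member of the group.
//
// STDP uses nearest-neighbour pairing via per-neuron last-spike times:
// at a presynaptic spike each outgoing EE synapse is depressed against the
// postsynaptic neuron's last spike, at a postsynaptic spike each incoming
// EE synapse is potentiated against the presynaptic neuron's last spike.
// Neurons spiking in the same time step pair with dt = 0 (no change).
// After every STDP-induced change the postsynaptic neuron's incoming EE
// weights are rescaled to L1 norm W_total.

static const double NEVER = -1e30;

// [[Rcpp::export]]
List cpp_sim_phase(List state, List par,
                   IntegerVector ee_pre, IntegerVector ee_post, NumericVector ee_w_in,
                   IntegerVector ei_pre, IntegerVector ei_post, NumericVector ei_w,
                   IntegerVector ie_pre, IntegerVector ie_post, NumericVector ie_w,
                   double duration_ms, double dt,
                   bool stdp_on, bool ip_on, bool noise_on,
                   NumericVector ext_time, IntegerVector ext_group,
                   List group_members, double input_w) {
  const int n_exc = as<int>(state["n_exc"]);
  const int n_inh = as<int>(state["n_inh"]);
  const int n = n_exc + n_inh;

  NumericVector v       = clone(as<NumericVector>(state["v"]));
  NumericVector g_ampa  = clone(as<NumericVector>(state["g_ampa"]));
  NumericVector g_gaba  = clone(as<NumericVector>(state["g_gaba"]));
  NumericVector v_th    = clone(as<NumericVector>(state["v_th"]));
  NumericVector refrac  = clone(as<NumericVector>(state["refrac"]));
  NumericVector xi      = clone(as<NumericVector>(state["xi"]));
  NumericVector last_sp = clone(as<NumericVector>(state["last_spike"]));
  double t = as<double>(state["t_ms"]);

  const double g_leak   = as<double>(par["g_leak"]);
  const double v_rest   = as<double>(par["v_rest"]);
  const double c_mem    = as<double>(par["c_membrane"]);
  const double tau_mem  = as<double>(par["tau_membrane"]);
  const double tau_ampa = as<double>(par["tau_ampa"]);
  const double tau_gaba = as<double>(par["tau_gaba"]);
  const double v_ampa   = as<double>(par["v_ampa"]);
  const double v_gaba   = as<double>(par["v_gaba"]);
  const double sigma    = as<double>(par["sigma_noise"]);
  const double tau_noise= as<double>(par["tau_noise"]);
  const double calib    = as<double>(par["noise_calib"]);
  const double eta_dec  = as<double>(par["eta_decay_ip"]) / 1000.0; // mV/s -> mV/ms
  const double eta_spk  = as<double>(par["eta_spike_ip"]);
  const double ref_E    = as<double>(par["tau_refrac_E"]);
  const double ref_I    = as<double>(par["tau_refrac_I"]);
  const double A_plus   = as<double>(par["A_plus"]);
  const double A_minus  = as<double>(par["A_minus"]);
  const double tau_plus = as<double>(par["tau_plus"]);
  const double tau_minus= as<double>(par["tau_minus"]);
  const double W_total  = as<double>(par["W_total"]);
  // optional outgoing-weight normalization (0 = off): after a presynaptic
  // spike's plasticity, the spiker's outgoing EE weights are rescaled to
  // this L1 target and every touched postsynaptic neuron is re-normalized,
  // so incoming sums remain exactly W_total
  const double W_out = par.containsElementNamed("W_total_out")
    ? as<double>(par["W_total_out"]) : 0.0;
  // depression semantics: subtractive (anti-causal pairings weaken the
  // synapse) or relative (anti-causal pairings also potentiate, by the
  // smaller exponential factor; depression is then purely the relative
  // loss under synaptic normalization)
  const bool depr_subtract = par.containsElementNamed("depression_subtractive")
    ? as<bool>(par["depression_subtractive"]) : true;

  NumericVector ee_w = clone(ee_w_in);
  const int n_ee = ee_pre.size(), n_ei = ei_pre.size(), n_ie = ie_pre.size();

  // CSR adjacency: EE by pre (propagation/depression), EE by post
  // (potentiation/normalization), EI by pre, IE by pre.
  std::vector<int> ee_by_pre_ptr(n_exc + 1, 0), ee_by_post_ptr(n_exc + 1, 0);
  for (int e = 0; e < n_ee; ++e) { ee_by_pre_ptr[ee_pre[e] + 1]++; ee_by_post_ptr[ee_post[e] + 1]++; }
  for (int i = 0; i < n_exc; ++i) { ee_by_pre_ptr[i + 1] += ee_by_pre_ptr[i]; ee_by_post_ptr[i + 1] += ee_by_post_ptr[i]; }
  std::vector<int> ee_by_pre(n_ee), ee_by_post(n_ee);
  {
    std::vector<int> cp(ee_by_pre_ptr.begin(), ee_by_pre_ptr.end() - 1);
    std::vector<int> cq(ee_by_post_ptr.begin(), ee_by_post_ptr.end() - 1);
    for (int e = 0; e < n_ee; ++e) { ee_by_pre[cp[ee_pre[e]]++] = e; ee_by_post[cq[ee_post[e]]++] = e; }
  }
  std::vector<int> ei_ptr(n_exc + 1, 0), ie_ptr(n_inh + 1, 0);
  for (int e = 0; e < n_ei; ++e) ei_ptr[ei_pre[e] + 1]++;
  for (int e = 0; e < n_ie; ++e) ie_ptr[ie_pre[e] - n_exc + 1]++;
  for (int i = 0; i < n_exc; ++i) ei_ptr[i + 1] += ei_ptr[i];
  for (int i = 0; i < n_inh; ++i) ie_ptr[i + 1] += ie_ptr[i];
  std::vector<int> ei_idx(n_ei), ie_idx(n_ie);
  {
    std::vector<int> cp(ei_ptr.begin(), ei_ptr.end() - 1), cq(ie_ptr.begin(), ie_ptr.end() - 1);
    for (int e = 0; e < n_ei; ++e) ei_idx[cp[ei_pre[e]]++] = e;
    for (int e = 0; e < n_ie; ++e) ie_idx[cq[ie_pre[e] - n_exc]++] = e;
  }

  std::vector< std::vector<int> > groups(group_members.size());
  for (int g = 0; g < group_members.size(); ++g) {
    IntegerVector m = group_members[g];
    groups[g] = std::vector<int>(m.begin(), m.end());
  }

  const double dec_ampa = 1.0 - dt / tau_ampa;
  const double dec_gaba = 1.0 - dt / tau_gaba;
  const double noise_amp = sigma * std::sqrt(2.0 * dt / tau_noise);

  const long n_steps = (long)std::floor(duration_ms / dt + 0.5);
  std::vector<double> sp_time; std::vector<int> sp_id;
  std::vector<int> spikers; spikers.reserve(64);
  std::vector<int> dirty; dirty.reserve(64);
  std::vector<char> is_dirty(n_exc, 0);
  int ext_ptr = 0;
  const int n_ext = ext_time.size();

  RNGScope rng;

  for (long step = 0; step < n_steps; ++step) {
    const double t_end = t + dt;

    // external input spikes due in this step
    while (ext_ptr < n_ext && ext_time[ext_ptr] < t_end) {
      const std::vector<int>& mem = groups[ext_group[ext_ptr]];
      for (size_t k = 0; k < mem.size(); ++k) g_ampa[mem[k]] += input_w;
      ++ext_ptr;
    }

    // integrate
    for (int j = 0; j < n; ++j) {
      if (noise_on) xi[j] += -xi[j] / tau_noise * dt + noise_amp * norm_rand();
      if (refrac[j] > 0.0) {
        refrac[j] -= dt;
        v[j] = v_rest;
      } else {
        const double dv = ((g_leak * (v_rest - v[j]) + g_ampa[j] * (v_ampa - v[j])
                            + g_gaba[j] * (v_gaba - v[j])) / c_mem
                           + calib * xi[j] / tau_mem) * dt;
        v[j] += dv;
        if (!std::isfinite(v[j]))
          stop("non-finite membrane voltage for neuron %d at t = %.2f ms", j + 1, t_end);
      }
      g_ampa[j] *= dec_ampa;
      g_gaba[j] *= dec_gaba;
      // intrinsic plasticity acts on the excitatory population only;
      // inhibitory thresholds are static
      if (ip_on && j < n_exc) v_th[j] -= eta_dec * dt;
    }

    // threshold crossings
    spikers.clear();
    for (int j = 0; j < n; ++j)
      if (refrac[j] <= 0.0 && v[j] > v_th[j]) spikers.push_back(j);

    if (!spikers.empty()) {
      dirty.clear();
      for (size_t s = 0; s < spikers.size(); ++s) {
        const int j = spikers[s];
        sp_time.push_back(t_end); sp_id.push_back(j);
        v[j] = v_rest;
        refrac[j] = (j < n_exc) ? ref_E : ref_I;
        if (ip_on && j < n_exc) v_th[j] += eta_spk;
        if (j < n_exc) {
          for (int q = ee_by_pre_ptr[j]; q < ee_by_pre_ptr[j + 1]; ++q) {
            const int e = ee_by_pre[q];
            const int post = ee_post[e];
            g_ampa[post] += ee_w[e];
            if (stdp_on && last_sp[post] > NEVER) {
              const double dtt = last_sp[post] - t_end; // <= 0
              if (dtt < 0.0) {
                const double dw = A_minus * std::exp(dtt / tau_minus);
                if (depr_subtract) {
                  ee_w[e] -= dw;
                  if (ee_w[e] < 0.0) ee_w[e] = 0.0;
                } else {
                  ee_w[e] += dw;
                }
                if (!is_dirty[post]) { is_dirty[post] = 1; dirty.push_back(post); }
              }
            }
          }
          for (int q = ei_ptr[j]; q < ei_ptr[j + 1]; ++q)
            g_ampa[ei_post[ei_idx[q]]] += ei_w[ei_idx[q]];
          if (stdp_on) {
            for (int q = ee_by_post_ptr[j]; q < ee_by_post_ptr[j + 1]; ++q) {
              const int e = ee_by_post[q];
              const int pre = ee_pre[e];
              if (last_sp[pre] > NEVER) {
                const double dtt = t_end - last_sp[pre]; // >= 0
                if (dtt > 0.0) {
                  ee_w[e] += A_plus * std::exp(-dtt / tau_plus);
                  if (!is_dirty[j]) { is_dirty[j] = 1; dirty.push_back(j); }
                }
              }
            }
          }
        } else {
          const int ji = j - n_exc;
          for (int q = ie_ptr[ji]; q < ie_ptr[ji + 1]; ++q)
            g_gaba[ie_post[ie_idx[q]]] += ie_w[ie_idx[q]];
        }
      }
      // outgoing normalization of excitatory spikers (marks targets dirty
      // so the incoming normalization below restores their sums exactly)
      if (stdp_on && W_out > 0.0) {
        for (size_t s = 0; s < spikers.size(); ++s) {
          const int j = spikers[s];
          if (j >= n_exc) continue;
          double osum = 0.0;
          for (int q = ee_by_pre_ptr[j]; q < ee_by_pre_ptr[j + 1]; ++q)
            osum += ee_w[ee_by_pre[q]];
          if (osum <= 0.0) continue;
          const double oscale = W_out / osum;
          for (int q = ee_by_pre_ptr[j]; q < ee_by_pre_ptr[j + 1]; ++q) {
            const int e = ee_by_pre[q];
            ee_w[e] *= oscale;
            const int post = ee_post[e];
            if (!is_dirty[post]) { is_dirty[post] = 1; dirty.push_back(post); }
          }
        }
      }
      // synaptic normalization of every postsynaptic neuron touched by STDP
      for (size_t d = 0; d < dirty.size(); ++d) {
        const int post = dirty[d];
        is_dirty[post] = 0;
        double sum = 0.0;
        for (int q = ee_by_post_ptr[post]; q < ee_by_post_ptr[post + 1]; ++q)
          sum += ee_w[ee_by_post[q]];
        if (sum > 0.0) {
          const double scale = W_total / sum;
          for (int q = ee_by_post_ptr[post]; q < ee_by_post_ptr[post + 1]; ++q)
            ee_w[ee_by_post[q]] *= scale;
        }
      }
      for (size_t s = 0; s < spikers.size(); ++s) last_sp[spikers[s]] = t_end;
    }

    t = t_end;
  }

  List out_state = List::create(
    _["v"] = v, _["g_ampa"] = g_ampa, _["g_gaba"] = g_gaba,
    _["v_th"] = v_th, _["refrac"] = refrac, _["xi"] = xi,
    _["last_spike"] = last_sp, _["t_ms"] = t,
    _["n_exc"] = n_exc, _["n_inh"] = n_inh);
  return List::create(_["state"] = out_state, _["ee_w"] = ee_w,
                      _["spike_time"] = wrap(sp_time), _["spike_id"] = wrap(sp_id));
}

// One-vs-rest perceptron. X is n x d (no intercept column; one is added),
// y in 0..K-1. Returns (d+1) x K weight matrix; scores = cbind(1, X) %*% W,
// prediction = argmax. Sample order is reshuffled every epoch with R's RNG.
// [[Rcpp::export]]
NumericMatrix cpp_perceptron_fit(NumericMatrix X, IntegerVector y, int K, int epochs) {
  const int n = X.nrow(), d = X.ncol();
  NumericMatrix W(d + 1, K);
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  RNGScope rng;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int i = n - 1; i > 0; --i) { // Fisher-Yates
      int j = (int)std::floor(unif_rand() * (i + 1));
      std::swap(ord[i], ord[j]);
    }
    for (int ii = 0; ii < n; ++ii) {
      const int i = ord[ii];
      for (int k = 0; k < K; ++k) {
        double score = W(0, k);
        for (int f = 0; f < d; ++f) score += W(f + 1, k) * X(i, f);
        const double yk = (y[i] == k) ? 1.0 : -1.0;
        if (yk * score <= 0.0) {
          W(0, k) += yk;
          for (int f = 0; f < d; ++f) W(f + 1, k) += yk * X(i, f);
        }
      }
    }
  }
  return W;
}
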
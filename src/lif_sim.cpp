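// Clock-driven conductance-based LIF network with optional Tsodyks-Markram
// short-term plasticity on every synapse.
//
// Units: ms, mV, nS, pF, pA. Conventions:
//  - forward Euler on the membrane, exact exponential decay of conductances;
//  - a presynaptic spike at step k increments the target conductance at the
//    start of step k+1 (one-step transmission delay) by g_max * W / tau_l
//    (static) or g_max * mu / tau_l (STP), tau_l in ms -- the integral of
//    the conductance equation across the spike with the delta in 1/ms;
//  - voltage is clamped at V_reset for t_ref after a spike while the
//    conductances keep integrating;
//  - no RNG here: topology, stimulus and initial voltages arrive from R, so
//    a run is a deterministic function of its inputs.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Arguments: edge_ptr is CSR by presynaptic neuron (0-based, length n+1)
// with 0-based targets edge_post and static weights edge_w; `neuron` holds
// C_m, g_leak, E_exc, E_inh, V_thresh, V_reset, V_rest, tau_exc, tau_inh,
// g_max_exc, g_max_inh, t_ref; V0 and I_ext (pA) are per neuron; stimulus
// events arrive as sorted 0-based steps with 0-based targets and
// conductance increments in nS (excitatory); the stp_* vectors are per
// edge (time constants in ms); record_idx names neurons whose V to record.
// [[Rcpp::export(name = ".lif_sim_cpp")]]
List lif_sim_cpp(int n, int n_exc,
                 IntegerVector edge_ptr,
                 IntegerVector edge_post,
                 NumericVector edge_w,
                 List neuron,
                 NumericVector V0,
                 NumericVector I_ext,
                 IntegerVector stim_step,
                 IntegerVector stim_target,
                 NumericVector stim_jump,
                 double duration, double dt,
                 bool use_stp,
                 NumericVector stp_U, NumericVector stp_tauF_ms,
                 NumericVector stp_tauD_ms, NumericVector stp_A,
                 IntegerVector record_idx,
                 bool stop_when_dead, double dead_window,
                 double rate_limit, double rate_window, double check_after,
                 int delay_steps) {
  const double C_m = neuron["C_m"], g_leak = neuron["g_leak"];
  const double E_exc = neuron["E_exc"], E_inh = neuron["E_inh"];
  const double V_thresh = neuron["V_thresh"], V_reset = neuron["V_reset"];
  const double V_rest = neuron["V_rest"];
  const double tau_exc = neuron["tau_exc"], tau_inh = neuron["tau_inh"];
  const double g_max_exc = neuron["g_max_exc"], g_max_inh = neuron["g_max_inh"];
  const double t_ref = neuron["t_ref"];

  const int n_steps = (int)std::llround(duration / dt);
  const double dec_e = std::exp(-dt / tau_exc), dec_i = std::exp(-dt / tau_inh);

  std::vector<double> V(V0.begin(), V0.end());
  std::vector<double> g_exc(n, 0.0), g_inh(n, 0.0);
  // ring buffer of pending conductance increments, one slot per delay step
  const int n_slots = std::max(1, delay_steps);
  std::vector<std::vector<double>> pend_exc(n_slots, std::vector<double>(n, 0.0));
  std::vector<std::vector<double>> pend_inh(n_slots, std::vector<double>(n, 0.0));
  std::vector<double> ref_until(n, -1.0);

  // STP per-edge state
  const int n_edges = edge_post.size();
  std::vector<double> su, sx, st_last;
  if (use_stp) {
    su.assign(n_edges, 0.0);
    sx.assign(n_edges, 1.0);
    st_last.assign(n_edges, 0.0);
  }

  std::vector<int> spk_neuron;
  std::vector<double> spk_time;
  spk_neuron.reserve(1 << 16);
  spk_time.reserve(1 << 16);

  const int n_rec = record_idx.size();
  NumericMatrix v_trace(n_rec > 0 ? n_steps + 1 : 0, n_rec);
  for (int j = 0; j < n_rec; ++j)
    if (n_rec > 0) v_trace(0, j) = V[record_idx[j]];

  // early-stop bookkeeping: spike counts over trailing windows
  const int dead_steps = stop_when_dead ? std::max(1, (int)std::llround(dead_window / dt)) : 0;
  const int rate_steps = R_finite(rate_limit) ? std::max(1, (int)std::llround(rate_window / dt)) : 0;
  long win_dead = 0, win_rate = 0;
  int dead_count = 0, rate_count = 0;
  bool stopped = false;
  std::string stop_reason = "";
  double stop_time = duration;

  int stim_i = 0;
  const int n_stim = stim_step.size();

  for (int k = 0; k < n_steps; ++k) {
    const double t_next = (k + 1) * dt;

    // conductance decay + synaptic arrivals due this step
    const int slot_now = k % n_slots;           // spikes queued delay steps ago
    std::vector<double> &arr_e = pend_exc[slot_now];
    std::vector<double> &arr_i = pend_inh[slot_now];
    for (int i = 0; i < n; ++i) {
      g_exc[i] = g_exc[i] * dec_e + arr_e[i];
      g_inh[i] = g_inh[i] * dec_i + arr_i[i];
      arr_e[i] = 0.0;
      arr_i[i] = 0.0;
    }
    // external stimulus events scheduled for this step
    while (stim_i < n_stim && stim_step[stim_i] == k) {
      g_exc[stim_target[stim_i]] += stim_jump[stim_i];
      ++stim_i;
    }
    while (stim_i < n_stim && stim_step[stim_i] < k) ++stim_i; // skip stale
    std::vector<double> &out_e = pend_exc[(k + delay_steps) % n_slots];
    std::vector<double> &out_i = pend_inh[(k + delay_steps) % n_slots];

    int spikes_this_step = 0;
    for (int i = 0; i < n; ++i) {
      if (t_next <= ref_until[i]) { V[i] = V_reset; continue; }
      double dV = (g_leak * (V_rest - V[i]) + g_exc[i] * (E_exc - V[i]) +
                   g_inh[i] * (E_inh - V[i]) + I_ext[i]) * (dt / C_m);
      V[i] += dV;
      if (V[i] >= V_thresh) {
        spk_neuron.push_back(i + 1);
        spk_time.push_back(t_next);
        V[i] = V_reset;
        ref_until[i] = t_next + t_ref;
        ++spikes_this_step;
        const bool pre_exc = i < n_exc;
        const double g_scale = pre_exc ? g_max_exc / tau_exc
                                       : g_max_inh / tau_inh;
        for (int e = edge_ptr[i]; e < edge_ptr[i + 1]; ++e) {
          double w;
          if (use_stp) {
            const double ddt = t_next - st_last[e];
            double u = su[e] * std::exp(-ddt / stp_tauF_ms[e]);
            double x = 1.0 - (1.0 - sx[e]) * std::exp(-ddt / stp_tauD_ms[e]);
            const double u1 = u * (1.0 - stp_U[e]) + stp_U[e];
            w = stp_A[e] * x * u1;
            su[e] = u1;
            sx[e] = x * (1.0 - u1);
            st_last[e] = t_next;
          } else {
            w = edge_w[e];
          }
          if (pre_exc) out_e[edge_post[e]] += g_scale * w;
          else         out_i[edge_post[e]] += g_scale * w;
        }
      }
      if (!std::isfinite(V[i]))
        stop("non-finite membrane potential at step %d (t = %.1f ms), neuron %d",
             k + 1, t_next, i + 1);
    }

    for (int j = 0; j < n_rec; ++j) v_trace(k + 1, j) = V[record_idx[j]];

    // early-stop checks on non-overlapping trailing windows
    if (dead_steps > 0 && t_next > check_after) {
      dead_count += spikes_this_step;
      if (++win_dead == dead_steps) {
        if (dead_count == 0) {
          stopped = true; stop_reason = "dead"; stop_time = t_next; break;
        }
        win_dead = 0; dead_count = 0;
      }
    }
    if (rate_steps > 0 && t_next > check_after) {
      rate_count += spikes_this_step;
      if (++win_rate == rate_steps) {
        const double rate = rate_count / ((double)n * rate_window / 1000.0);
        if (rate > rate_limit) {
          stopped = true; stop_reason = "saturated"; stop_time = t_next; break;
        }
        win_rate = 0; rate_count = 0;
      }
    }
    if (k % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["neuron"] = wrap(spk_neuron),
                      _["time"] = wrap(spk_time),
                      _["v_trace"] = v_trace,
                      _["stopped_early"] = stopped,
                      _["stop_reason"] = stop_reason,
                      _["sim_duration"] = stop_time);
}
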
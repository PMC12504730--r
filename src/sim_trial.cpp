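#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Clock-driven simulation of one trial of the channelized striatal circuit.
//
// Populations: per channel `n_d1` D1 SPNs, `n_d2` D2 SPNs and one action
// neuron. All neurons are leaky integrate-and-fire with current-based delta
// synapses; refractory neurons are clamped at reset and ignore input.
//
// Update order within a step (time now = t*dt):
//   1. decay traces and membranes (refractory clamp),
//   2. deliver external input spikes (membrane kicks, post-before-pre
//      eligibility, then x_pre += 1, so dt=0 pairs count as pre-before-post),
//   3. lateral inhibition from the previous step's SPN spikes, noise, i_ext,
//   4. SPN threshold crossing: reset, refractory, y_post += 1,
//      pre-before-post eligibility gated by the channel's ACh gate,
//   5. action neurons driven by this step's SPN spikes; an action spike
//      opens (or extends) the channel's ACh gate for `ach_window` ms.
//
// Eligibility is accumulated as two raw coincidence sums per synapse
// (E*_prepost: sum over post spikes of x_pre; E*_postpre: sum over pre
// spikes of y_post); STDP kernel amplitudes are applied later, at dopamine
// delivery. A pairing counts only if the *later* spike of the pair falls
// inside an open gate of the postsynaptic neuron's channel (or always, when
// `gated` is false).

// [[Rcpp::export]]
List sim_trial_cpp(IntegerVector in_step, IntegerVector in_id,
                   int n_in, int n_channels, int n_d1, int n_d2,
                   NumericMatrix W1, NumericMatrix W2,
                   double tau_m, double tau_m_act,
                   double v_th_d1, double v_th_d2,
                   double v_th_act, double v_reset, int ref_steps,
                   double w_d1_act, double w_d2_act, double w_act_act,
                   double w_d2_d1, double w_d1_d2, double lat_cross_frac,
                   double sigma_spn, double sigma_act,
                   double i_ext_d1, double i_ext_d2, double i_ext_act,
                   int n_steps, double dt,
                   double ach_window, bool gated,
                   double tau_plus, double tau_minus,
                   bool accumulate, bool record_spikes) {
  const int n1 = n_channels * n_d1;
  const int n2 = n_channels * n_d2;
  const double dm = std::exp(-dt / tau_m);
  const double dma = std::exp(-dt / tau_m_act);
  const double dp = std::exp(-dt / tau_plus);
  const double dq = std::exp(-dt / tau_minus);

  std::vector<double> v1(n1, v_reset), v2(n2, v_reset), va(n_channels, v_reset);
  std::vector<int> r1(n1, 0), r2(n2, 0), ra(n_channels, 0);
  std::vector<char> f1(n1, 0), f2(n2, 0), fa(n_channels, 0); // refractory this step
  std::vector<double> xpre(n_in, 0.0), y1(n1, 0.0), y2(n2, 0.0);
  std::vector<double> gate_until(n_channels, -1.0);
  std::vector<int> gate_last(n_channels, -1);

  NumericMatrix E1p, E1q, E2p, E2q;
  if (accumulate) {
    E1p = NumericMatrix(n_in, n1); E1q = NumericMatrix(n_in, n1);
    E2p = NumericMatrix(n_in, n2); E2q = NumericMatrix(n_in, n2);
  }
  IntegerVector cnt1(n1), cnt2(n2);
  std::vector<double> act_time; std::vector<int> act_ch;
  std::vector<double> sp_t; std::vector<int> sp_id, sp_pop;
  std::vector<double> g_ch, g_open, g_close;
  std::vector<int> d1_now(n_channels), d2_now(n_channels);

  int prev_d1 = 0, prev_d2 = 0;
  std::vector<int> prev_d1_ch(n_channels, 0), prev_d2_ch(n_channels, 0);
  int ip = 0;
  const int n_spk = in_step.size();
  std::vector<char> gopen(n_channels, 0);

  for (int t = 0; t < n_steps; ++t) {
    const double now = t * dt;

    // 1. decay / refractory clamp
    for (int i = 0; i < n_in; ++i) xpre[i] *= dp;
    for (int j = 0; j < n1; ++j) {
      y1[j] *= dq;
      if (r1[j] > 0) { --r1[j]; v1[j] = v_reset; f1[j] = 1; }
      else { v1[j] *= dm; f1[j] = 0; }
    }
    for (int j = 0; j < n2; ++j) {
      y2[j] *= dq;
      if (r2[j] > 0) { --r2[j]; v2[j] = v_reset; f2[j] = 1; }
      else { v2[j] *= dm; f2[j] = 0; }
    }
    for (int c = 0; c < n_channels; ++c) {
      if (ra[c] > 0) { --ra[c]; va[c] = v_reset; fa[c] = 1; }
      else { va[c] *= dma; fa[c] = 0; }
      gopen[c] = (gate_until[c] >= now) ? 1 : 0;
    }

    // 2. external input spikes
    while (ip < n_spk && in_step[ip] == t) {
      const int id = in_id[ip];
      if (accumulate) {
        for (int j = 0; j < n1; ++j)
          if (!gated || gopen[j / n_d1]) E1q(id, j) += y1[j];
        for (int j = 0; j < n2; ++j)
          if (!gated || gopen[j / n_d2]) E2q(id, j) += y2[j];
      }
      for (int j = 0; j < n1; ++j) if (!f1[j]) v1[j] += W1(id, j);
      for (int j = 0; j < n2; ++j) if (!f2[j]) v2[j] += W2(id, j);
      xpre[id] += 1.0;
      ++ip;
    }

    // 3. lateral inhibition (previous step's spikes; full weight within the
    //    channel, lat_cross_frac of it across channels), noise, i_ext
    for (int j = 0; j < n1; ++j) {
      if (f1[j]) continue;
      if (prev_d2 > 0) {
        const int own = prev_d2_ch[j / n_d1];
        v1[j] += w_d2_d1 * (own + lat_cross_frac * (prev_d2 - own));
      }
      if (sigma_spn > 0) v1[j] += sigma_spn * norm_rand();
      v1[j] += i_ext_d1;
    }
    for (int j = 0; j < n2; ++j) {
      if (f2[j]) continue;
      if (prev_d1 > 0) {
        const int own = prev_d1_ch[j / n_d2];
        v2[j] += w_d1_d2 * (own + lat_cross_frac * (prev_d1 - own));
      }
      if (sigma_spn > 0) v2[j] += sigma_spn * norm_rand();
      v2[j] += i_ext_d2;
    }

    // 4. SPN threshold crossing
    std::fill(d1_now.begin(), d1_now.end(), 0);
    std::fill(d2_now.begin(), d2_now.end(), 0);
    for (int j = 0; j < n1; ++j) {
      if (f1[j]) continue;
      if (!std::isfinite(v1[j])) stop("non-finite membrane potential (D1)");
      if (v1[j] >= v_th_d1) {
        v1[j] = v_reset; r1[j] = ref_steps;
        y1[j] += 1.0; ++cnt1[j]; ++d1_now[j / n_d1];
        if (accumulate && (!gated || gopen[j / n_d1]))
          for (int i = 0; i < n_in; ++i) E1p(i, j) += xpre[i];
        if (record_spikes) { sp_t.push_back(now); sp_id.push_back(j); sp_pop.push_back(0); }
      }
    }
    for (int j = 0; j < n2; ++j) {
      if (f2[j]) continue;
      if (!std::isfinite(v2[j])) stop("non-finite membrane potential (D2)");
      if (v2[j] >= v_th_d2) {
        v2[j] = v_reset; r2[j] = ref_steps;
        y2[j] += 1.0; ++cnt2[j]; ++d2_now[j / n_d2];
        if (accumulate && (!gated || gopen[j / n_d2]))
          for (int i = 0; i < n_in; ++i) E2p(i, j) += xpre[i];
        if (record_spikes) { sp_t.push_back(now); sp_id.push_back(j); sp_pop.push_back(1); }
      }
    }

    // 5. action neurons (feedforward within the step); an action spike
    //    inhibits the other channels' action neurons (winner-take-all race)
    int act_now = -1;
    for (int c = 0; c < n_channels; ++c) {
      if (fa[c]) continue;
      va[c] += w_d1_act * d1_now[c] + w_d2_act * d2_now[c] + i_ext_act;
      if (act_now >= 0) va[c] += w_act_act;
      if (sigma_act > 0) va[c] += sigma_act * norm_rand();
      if (!std::isfinite(va[c])) stop("non-finite membrane potential (action)");
      if (va[c] >= v_th_act) {
        va[c] = v_reset; ra[c] = ref_steps;
        if (act_now < 0 && w_act_act != 0)
          for (int k = 0; k < c; ++k) if (!fa[k]) va[k] += w_act_act;
        act_now = c;
        act_time.push_back(now); act_ch.push_back(c);
        if (record_spikes) { sp_t.push_back(now); sp_id.push_back(c); sp_pop.push_back(2); }
        const double new_close = now + ach_window;
        if (gate_last[c] >= 0 && gate_until[c] >= now) {
          g_close[gate_last[c]] = new_close;       // refresh extends, not stacks
        } else {
          g_ch.push_back(c); g_open.push_back(now); g_close.push_back(new_close);
          gate_last[c] = (int)g_ch.size() - 1;
        }
        gate_until[c] = new_close;
      }
    }

    prev_d1 = 0; prev_d2 = 0;
    for (int c = 0; c < n_channels; ++c) {
      prev_d1 += d1_now[c]; prev_d2 += d2_now[c];
      prev_d1_ch[c] = d1_now[c]; prev_d2_ch[c] = d2_now[c];
    }
  }

  List out = List::create(
    _["action_time"] = wrap(act_time),
    _["action_channel"] = wrap(act_ch),
    _["d1_count"] = cnt1,
    _["d2_count"] = cnt2,
    _["gates"] = DataFrame::create(_["channel"] = wrap(g_ch),
                                   _["open"] = wrap(g_open),
                                   _["close"] = wrap(g_close)));
  if (accumulate) {
    out["E1_prepost"] = E1p; out["E1_postpre"] = E1q;
    out["E2_prepost"] = E2p; out["E2_postpre"] = E2q;
  }
  if (record_spikes)
    out["spikes"] = DataFrame::create(_["time_ms"] = wrap(sp_t),
                                      _["neuron_id"] = wrap(sp_id),
                                      _["population"] = wrap(sp_pop));
  return out;
}
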
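#include <Rcpp.h>
using namespace Rcpp;

// Adaptive exponential integrate-and-fire with a hyperpolarization-activated
// sag conductance and a stylized (raised-sine) spike waveform.
//
// Units: mV, ms, pA, pF, nS.  C dV/dt [pF*mV/ms] = pA, so no conversion
// factors are needed.  Uses R's RNG so set.seed() controls the noise.
//
// When V crosses the numerical spike cutoff (v_thresh + 5*delta_t) the next
// rise_ms + decay_ms of trace are overwritten with a sin^2 rise of height
// spike_amp_mv followed by a sin^2 decay of depth spike_amp_mv + ahp_mv;
// integration resumes from v_start - ahp_mv with the adaptation current
// incremented.  The waveform duration acts as the absolute refractory period.

// [[Rcpp::export]]
List adex_integrate_cpp(NumericVector current_pa, double dt_ms,
                        double cap_pf, double g_leak_ns, double e_leak_mv,
                        double v_thresh_mv, double delta_t_mv,
                        double adapt_b_pa, double adapt_tau_ms,
                        double spike_amp_mv, double rise_ms, double decay_ms,
                        double ahp_mv,
                        double g_sag_ns, double sag_tau_ms, double e_sag_mv,
                        double sag_vhalf_mv, double sag_k_mv,
                        double noise_sd_mv) {
  const int n = current_pa.size();
  NumericVector v(n);
  std::vector<double> spike_onsets;

  const double tau_m = cap_pf / g_leak_ns;
  const double noise_scale = noise_sd_mv * std::sqrt(2.0 * dt_ms / tau_m);
  const double v_cut = v_thresh_mv + 5.0 * delta_t_mv;

  // start at the passive equilibrium
  double V = e_leak_mv;
  double s = 1.0 / (1.0 + std::exp((V - sag_vhalf_mv) / sag_k_mv));
  if (g_sag_ns > 0.0) {
    // one fixed-point refinement so the pre-stimulus drift is negligible
    for (int it = 0; it < 50; ++it) {
      double si = 1.0 / (1.0 + std::exp((V - sag_vhalf_mv) / sag_k_mv));
      double Vn = (g_leak_ns * e_leak_mv + g_sag_ns * si * e_sag_mv) /
                  (g_leak_ns + g_sag_ns * si);
      if (std::fabs(Vn - V) < 1e-10) { V = Vn; s = si; break; }
      V = Vn; s = si;
    }
  }
  double w = 0.0;

  // waveform sampled at the true (continuous) rise/decay durations so spike
  // width varies smoothly with the gains rather than in dt-sized jumps
  const int n_wave = std::max(2, (int) std::floor((rise_ms + decay_ms) / dt_ms));

  int i = 0;
  while (i < n) {
    v[i] = V;
    double s_inf = 1.0 / (1.0 + std::exp((V - sag_vhalf_mv) / sag_k_mv));
    s += dt_ms * (s_inf - s) / sag_tau_ms;
    if (adapt_tau_ms > 0.0) w += dt_ms * (-w / adapt_tau_ms);

    double i_exp = 0.0;
    if (delta_t_mv > 0.0) {
      double ex = (V - v_thresh_mv) / delta_t_mv;
      if (ex > 20.0) ex = 20.0;
      i_exp = g_leak_ns * delta_t_mv * std::exp(ex);
    }
    double dv = (-g_leak_ns * (V - e_leak_mv) + i_exp +
                 g_sag_ns * s * (e_sag_mv - V) - w + current_pa[i]) / cap_pf;
    V += dt_ms * dv;
    if (noise_scale > 0.0) V += noise_scale * norm_rand();

    if (V >= v_cut) {
      double v_start = v_cut;
      double v_peak = v_start + spike_amp_mv;
      spike_onsets.push_back(i * dt_ms);
      int j;
      for (j = 1; j <= n_wave && i + j < n; ++j) {
        double t = j * dt_ms;
        if (t <= rise_ms) {
          double ph = std::sin(M_PI * t / (2.0 * rise_ms));
          v[i + j] = v_start + spike_amp_mv * ph * ph;
        } else {
          double ph = std::sin(M_PI * (t - rise_ms) / (2.0 * decay_ms));
          v[i + j] = v_peak - (spike_amp_mv + ahp_mv) * ph * ph;
        }
      }
      i += n_wave;
      if (i >= n) break;
      V = v_start - ahp_mv;
      w += adapt_b_pa;
      ++i;
      continue;
    }
    ++i;
  }

  return List::create(_["voltage_mv"] = v,
                      _["spike_onset_ms"] = wrap(spike_onsets));
}
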
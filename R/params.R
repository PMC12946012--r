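#' Intrinsic parameters of a model interneuron
#'
#' Builds the parameter set of the adaptive exponential integrate-and-fire
#' neuron used by [simulate_current_steps()]. The two built-in parameter sets
#' (`cell_class = "FS"` / `"nonFS"`) are calibrated so that feature extraction
#' on simulated current-step recordings reproduces the passive and
#' action-potential statistics typical of fast-spiking and non-fast-spiking
#' cortical interneurons (narrow vs. broad spikes, low vs. high input
#' resistance, small vs. large sag, low vs. high rheobase).
#'
#' The spike waveform is stylized: once the membrane passes threshold, a
#' raised-sine rise of height `spike_amplitude` and a raised-sine decay of
#' depth `spike_amplitude + ahp_depth` are emitted. The rise and decay
#' durations are derived from `spike_upstroke_gain` and
#' `spike_repolarization_gain` (the maximal dV/dt of the two phases), so spike
#' width and dV/dt extrema are controlled directly by interpretable
#' parameters.
#'
#' @param cell_class `"FS"` or `"nonFS"`; selects the calibrated default set.
#' @param membrane_capacitance pF.
#' @param leak_conductance nS; input resistance is `1/leak_conductance`.
#' @param leak_reversal mV; passive resting potential.
#' @param spike_threshold mV; threshold parameter of the exponential term.
#' @param spike_threshold_slope_factor mV; sharpness of spike initiation.
#' @param adaptation_increment pA added to the adaptation current per spike.
#' @param adaptation_time_constant ms; decay of the adaptation current.
#' @param spike_upstroke_gain mV/ms; maximal rate of rise of the spike.
#' @param spike_repolarization_gain mV/ms; maximal (absolute) rate of decay.
#' @param spike_amplitude mV; spike height above threshold.
#' @param ahp_depth mV; after-hyperpolarization below the spike take-off point.
#' @param sag_conductance nS; hyperpolarization-activated (sag) conductance.
#' @param sag_time_constant ms; activation time constant of the sag current.
#' @param sag_reversal mV; reversal potential of the sag current.
#' @param sag_vhalf,sag_slope mV; half-activation voltage and slope of the
#'   sag activation curve (activates below `sag_vhalf`).
#' @param noise_sd mV; stationary standard deviation of membrane noise.
#'
#' @return An object of class `neuron_params` (a named list).
#' @examples
#' neuron_params("FS")
#' neuron_params("nonFS", noise_sd = 0)
#' @export
neuron_params <- function(cell_class = c("FS", "nonFS"),
                          membrane_capacitance = NULL,
                          leak_conductance = NULL,
                          leak_reversal = NULL,
                          spike_threshold = NULL,
                          spike_threshold_slope_factor = 1,
                          adaptation_increment = NULL,
                          adaptation_time_constant = NULL,
                          spike_upstroke_gain = NULL,
                          spike_repolarization_gain = NULL,
                          spike_amplitude = NULL,
                          ahp_depth = NULL,
                          sag_conductance = NULL,
                          sag_time_constant = NULL,
                          sag_reversal = -40,
                          sag_vhalf = NULL,
                          sag_slope = 6,
                          noise_sd = 0.3) {
  cell_class <- match.arg(cell_class)
  d <- .neuron_defaults[[cell_class]]
  p <- list(
    cell_class = cell_class,
    membrane_capacitance = membrane_capacitance %||% d$membrane_capacitance,
    leak_conductance = leak_conductance %||% d$leak_conductance,
    leak_reversal = leak_reversal %||% d$leak_reversal,
    spike_threshold = spike_threshold %||% d$spike_threshold,
    spike_threshold_slope_factor = spike_threshold_slope_factor,
    adaptation_increment = adaptation_increment %||% d$adaptation_increment,
    adaptation_time_constant = adaptation_time_constant %||% d$adaptation_time_constant,
    spike_upstroke_gain = spike_upstroke_gain %||% d$spike_upstroke_gain,
    spike_repolarization_gain = spike_repolarization_gain %||% d$spike_repolarization_gain,
    spike_amplitude = spike_amplitude %||% d$spike_amplitude,
    ahp_depth = ahp_depth %||% d$ahp_depth,
    sag_conductance = sag_conductance %||% d$sag_conductance,
    sag_time_constant = sag_time_constant %||% d$sag_time_constant,
    sag_reversal = sag_reversal,
    sag_vhalf = sag_vhalf %||% d$sag_vhalf,
    sag_slope = sag_slope,
    noise_sd = noise_sd
  )
  validate_neuron_params(p)
  structure(p, class = "neuron_params")
}

# Calibrated so that extracted cohort feature means land near the FS / non-FS
# summary statistics the generator is meant to emulate (see
# scripts/calibrate_defaults.R for the calibration procedure).
.neuron_defaults <- list(
  FS = list(
    membrane_capacitance = 72.75,
    leak_conductance = 9.732,
    leak_reversal = -64.37,
    spike_threshold = -55.34,
    adaptation_increment = 8,
    adaptation_time_constant = 60,
    spike_upstroke_gain = 852.8,
    spike_repolarization_gain = 868.8,
    spike_amplitude = 96.4,
    ahp_depth = 12,
    sag_conductance = 4.297,
    sag_vhalf = -75,
    sag_time_constant = 40
  ),
  nonFS = list(
    membrane_capacitance = 68.61,
    leak_conductance = 4.761,
    leak_reversal = -62.25,
    spike_threshold = -22.71,
    adaptation_increment = 60,
    adaptation_time_constant = 150,
    spike_upstroke_gain = 468.2,
    spike_repolarization_gain = 219.6,
    spike_amplitude = 79.27,
    ahp_depth = 10,
    sag_conductance = 5.023,
    sag_vhalf = -72,
    sag_time_constant = 100
  )
)

validate_neuron_params <- function(p) {
  stopifnot(is.list(p))
  if (!is.finite(p$membrane_capacitance) || p$membrane_capacitance <= 0)
    stop("membrane_capacitance must be > 0", call. = FALSE)
  if (!is.finite(p$leak_conductance) || p$leak_conductance <= 0)
    stop("leak_conductance must be > 0", call. = FALSE)
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (p$sag_conductance < 0) stop("sag_conductance must be >= 0", call. = FALSE)
  if (p$spike_upstroke_gain <= 0 || p$spike_repolarization_gain <= 0)
    stop("spike waveform gains must be > 0", call. = FALSE)
  if (p$spike_amplitude <= 0) stop("spike_amplitude must be > 0", call. = FALSE)
  invisible(p)
}

#' Current-step stimulation protocol
#'
#' Defaults follow the standard characterization protocol: 800 ms square
#' steps from -100 pA in +20 pA increments, one step per sweep.
#'
#' @param step_duration ms.
#' @param start_current pA of the first (most hyperpolarizing) step.
#' @param increment pA added per sweep.
#' @param n_steps number of sweeps.
#' @param sampling_rate kHz.
#' @param pre_ms,post_ms ms of pre- and post-step recording per sweep.
#' @return An object of class `step_protocol`.
#' @export
step_protocol <- function(step_duration = 800, start_current = -100,
                          increment = 20, n_steps = 21,
                          sampling_rate = 50, pre_ms = 100, post_ms = 200) {
  if (sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  if (step_duration <= 0 || n_steps < 1) stop("invalid step protocol", call. = FALSE)
  structure(list(step_duration = step_duration, start_current = start_current,
                 increment = increment, n_steps = n_steps,
                 sampling_rate = sampling_rate, pre_ms = pre_ms,
                 post_ms = post_ms),
            class = "step_protocol")
}

#' Paired-pulse stimulation protocol
#'
#' Two presynaptic stimuli per sweep, 60 ms apart by default, one sweep every
#' 10 s. The 50 ms interval used in some experiments is available via
#' `interpulse_interval = 50`.
#'
#' @param interpulse_interval ms between the two stimuli.
#' @param sweep_period s between sweep starts.
#' @param n_sweeps total number of sweeps in the recording.
#' @param holding_potential mV command potential of the postsynaptic cell.
#' @param sampling_rate kHz.
#' @param sweep_duration ms; single-sweep trace length.
#' @param stim1_ms ms; time of the first stimulus within the sweep.
#' @param test_pulse_start,test_pulse_duration ms; window of the -5 mV
#'   input-resistance test pulse inserted in each sweep (`NULL` to disable).
#' @param test_pulse_mv mV amplitude of the test pulse (negative).
#' @return An object of class `pair_protocol`.
#' @export
pair_protocol <- function(interpulse_interval = 60, sweep_period = 10,
                          n_sweeps = 30, holding_potential = -65,
                          sampling_rate = 25, sweep_duration = 160,
                          stim1_ms = 20,
                          test_pulse_start = 110, test_pulse_duration = 40,
                          test_pulse_mv = -5) {
  if (sampling_rate <= 0) stop("sampling_rate must be > 0", call. = FALSE)
  if (interpulse_interval <= 0 || sweep_period <= 0 || n_sweeps < 1)
    stop("invalid pair protocol", call. = FALSE)
  if (stim1_ms + interpulse_interval + 20 > sweep_duration)
    stop("sweep too short for the paired stimuli", call. = FALSE)
  structure(list(interpulse_interval = interpulse_interval,
                 sweep_period = sweep_period, n_sweeps = n_sweeps,
                 holding_potential = holding_potential,
                 sampling_rate = sampling_rate,
                 sweep_duration = sweep_duration, stim1_ms = stim1_ms,
                 test_pulse_start = test_pulse_start,
                 test_pulse_duration = test_pulse_duration,
                 test_pulse_mv = test_pulse_mv),
            class = "pair_protocol")
}

#' Parameters of a model pyramidal-cell to interneuron synapse
#'
#' Multi-site binomial quantal release with paired-pulse dynamics. Each
#' stimulus releases `Binomial(available sites, p)` quanta; released sites
#' depress (become unavailable with probability `depression_fraction`) and
#' recover with time constant `recovery_time_constant`, while release
#' probability is transiently facilitated for the second pulse. Defaults are
#' calibrated for a connection onto a fast-spiking interneuron: mean
#' first-pulse EPSC near 62 pA, rare failures, a near-neutral baseline
#' paired-pulse ratio (sweep-ratio mean ~1.03), and synaptic latency
#' 0.98 +/- 0.21 ms.
#'
#' @param n_sites number of independent release sites.
#' @param release_prob_baseline per-site release probability in [0, 1].
#' @param quantal_amp pA; peak EPSC of a single quantum.
#' @param facilitation_increment fractional increase of the release
#'   probability at the second pulse: `p2 = min(1, p * (1 + f))`.
#' @param recovery_time_constant ms; recovery from depression.
#' @param depression_fraction probability in [0, 1] that a released site is
#'   unavailable immediately after release.
#' @param latency_mean,latency_sd ms; synaptic latency distribution
#'   (presynaptic spike peak to EPSC onset), truncated at `latency_min`.
#' @param latency_min ms; lower truncation of latency draws.
#' @param rise_tau,decay_tau ms; EPSC difference-of-exponentials kinetics.
#' @param noise_sd_current pA; additive white current noise.
#' @return An object of class `synapse_params`.
#' @examples
#' synapse_params()
#' synapse_params(release_prob_baseline = 1, noise_sd_current = 0)
#' @export
synapse_params <- function(n_sites = 20,
                           release_prob_baseline = 0.50,
                           quantal_amp = 6.3,
                           facilitation_increment = 0.31,
                           recovery_time_constant = 120,
                           depression_fraction = 0.90,
                           latency_mean = 0.98,
                           latency_sd = 0.21,
                           latency_min = 0.3,
                           rise_tau = 0.2,
                           decay_tau = 2,
                           noise_sd_current = 2) {
  p <- list(n_sites = n_sites, release_prob_baseline = release_prob_baseline,
            quantal_amp = quantal_amp,
            facilitation_increment = facilitation_increment,
            recovery_time_constant = recovery_time_constant,
            depression_fraction = depression_fraction,
            latency_mean = latency_mean, latency_sd = latency_sd,
            latency_min = latency_min,
            rise_tau = rise_tau, decay_tau = decay_tau,
            noise_sd_current = noise_sd_current)
  validate_synapse_params(p)
  structure(p, class = "synapse_params")
}

validate_synapse_params <- function(p) {
  if (p$n_sites < 1 || p$n_sites != round(p$n_sites))
    stop("n_sites must be a positive integer", call. = FALSE)
  if (p$release_prob_baseline < 0 || p$release_prob_baseline > 1)
    stop("release_prob_baseline must be in [0, 1]", call. = FALSE)
  if (p$quantal_amp <= 0) stop("quantal_amp must be > 0", call. = FALSE)
  if (p$depression_fraction < 0 || p$depression_fraction > 1)
    stop("depression_fraction must be in [0, 1]", call. = FALSE)
  if (p$facilitation_increment < 0 || p$facilitation_increment > 1)
    stop("facilitation_increment must be in [0, 1]", call. = FALSE)
  if (p$rise_tau >= p$decay_tau)
    stop("rise_tau must be smaller than decay_tau", call. = FALSE)
  if (p$latency_sd < 0) stop("latency_sd must be >= 0", call. = FALSE)
  if (p$noise_sd_current < 0) stop("noise_sd_current must be >= 0", call. = FALSE)
  invisible(p)
}

#' Neuromodulation scenario
#'
#' Describes how agonist application changes the model between `onset_time`
#' and `washout_time`:
#' * `presynaptic_p_scale` multiplies the release probability,
#' * `postsynaptic_q_scale` multiplies the quantal amplitude,
#' * `leak_block` multiplies the leak conductance of the postsynaptic cell by
#'   `leak_scale` (shifting holding current and input resistance),
#' * `mixed` combines `presynaptic_p_scale` and `leak_block`,
#' * `none` leaves everything unchanged.
#'
#' @param mechanism one of `"none"`, `"presynaptic_p_scale"`,
#'   `"postsynaptic_q_scale"`, `"leak_block"`, `"mixed"`.
#' @param scale_factor multiplicative change of the targeted quantity (> 0).
#' @param onset_time s; start of agonist action.
#' @param washout_time s or `NA`; end of agonist action.
#' @param leak_scale in (0, 1]; factor applied to the leak conductance for
#'   `leak_block` / `mixed`.
#' @return An object of class `modulation_scenario`.
#' @export
modulation_scenario <- function(mechanism = c("none", "presynaptic_p_scale",
                                              "postsynaptic_q_scale",
                                              "leak_block", "mixed"),
                                scale_factor = 1,
                                onset_time = 0,
                                washout_time = NA_real_,
                                leak_scale = 1) {
  mechanism <- match.arg(mechanism)
  if (!is.finite(scale_factor) || scale_factor <= 0)
    stop("scale_factor must be > 0", call. = FALSE)
  if (mechanism == "none" && scale_factor != 1)
    stop("mechanism 'none' requires scale_factor = 1", call. = FALSE)
  if (leak_scale <= 0 || leak_scale > 1)
    stop("leak_scale must be in (0, 1]", call. = FALSE)
  if (!is.na(washout_time) && washout_time <= onset_time)
    stop("washout_time must come after onset_time", call. = FALSE)
  structure(list(mechanism = mechanism, scale_factor = scale_factor,
                 onset_time = onset_time, washout_time = washout_time,
                 leak_scale = leak_scale),
            class = "modulation_scenario")
}

#' Apply a leak-block modulation to neuron parameters
#'
#' Under `leak_block` (or `mixed`) modulation the leak conductance is
#' multiplied by `leak_scale`. The implied input resistance scales by
#' `1/leak_scale` and the implied holding current at a fixed clamp potential
#' shifts by `(V_hold - leak_reversal) * (g_new - g_old)`.
#'
#' @param params a [neuron_params()] object.
#' @param mod a [modulation_scenario()] with mechanism `leak_block` or
#'   `mixed`.
#' @return A `neuron_params` object with the scaled leak conductance.
#' @examples
#' p <- neuron_params("FS")
#' m <- modulation_scenario("leak_block", leak_scale = 0.8)
#' apply_modulation_effect(p, m)$leak_conductance / p$leak_conductance
#' @export
apply_modulation_effect <- function(params, mod) {
  stopifnot(inherits(params, "neuron_params"),
            inherits(mod, "modulation_scenario"))
  if (!mod$mechanism %in% c("leak_block", "mixed"))
    stop("apply_modulation_effect requires a leak_block (or mixed) scenario",
         call. = FALSE)
  params$leak_conductance <- params$leak_conductance * mod$leak_scale
  params
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params> class:", x$cell_class,
      sprintf("| C = %.1f pF, gL = %.2f nS (Rin = %.1f MOhm), EL = %.1f mV\n",
              x$membrane_capacitance, x$leak_conductance,
              1000 / x$leak_conductance, x$leak_reversal))
  invisible(x)
}

#' @export
print.synapse_params <- function(x, ...) {
  cat(sprintf(
    "<synapse_params> n = %d sites, p = %.2f, q = %.1f pA (mean EPSC %.1f pA)\n",
    x$n_sites, x$release_prob_baseline, x$quantal_amp,
    x$n_sites * x$release_prob_baseline * x$quantal_amp))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
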
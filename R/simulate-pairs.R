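#' Simulate a paired recording (presynaptic spikes + postsynaptic EPSCs)
#'
#' Generates the postsynaptic current sweeps of a paired-pulse experiment.
#' Each stimulus triggers a presynaptic action potential; released quanta are
#' drawn from a binomial law over release sites whose availability evolves by
#' depression/recovery between the paired pulses and whose release
#' probability is transiently facilitated at the second pulse. The EPSC
#' waveform is a difference of exponentials scaled by the released quanta,
#' with per-event latency jitter and additive current noise. A modulation
#' scenario multiplies release probability (`presynaptic_p_scale`) or quantal
#' amplitude (`postsynaptic_q_scale`) from onset to washout; `leak_block`
#' (and `mixed`) scales the postsynaptic leak conductance, shifting holding
#' current and input resistance.
#'
#' Every sweep also carries a holding-current estimate, an access-resistance
#' reading (slow random walk, optionally with a step increase for QC
#' exercises), and an input-resistance test pulse; a 1 Hz holding-current
#' series spanning the whole experiment is attached for time-course
#' analysis.
#'
#' @param syn a [synapse_params()] object.
#' @param mod a [modulation_scenario()]; `onset_time`/`washout_time` are in
#'   seconds of experiment time.
#' @param protocol a [pair_protocol()].
#' @param seed integer seed (bit-reproducible output).
#' @param pair_id identifier.
#' @param holding a [holding_model()] describing the postsynaptic leak seen
#'   under voltage clamp.
#' @param access_step optional list(`sweep`, `delta_mohm`) adding a step
#'   increase to the access-resistance series.
#' @return A list of class `paired_recording` with elements `sweeps` (tibble:
#'   `sweep`, `time_s`, `epoch`, `stim1_ms`, `stim2_ms`, `presyn_ap1_ms`,
#'   `presyn_ap2_ms`, `access_mohm`, `holding_pa`, `trace` list-column of pA
#'   series), `holding` (tibble `time_s`, `current_pa`), `protocol`,
#'   `ground_truth` (generator parameters, scenario, per-sweep released
#'   quanta and true latencies, true category).
#' @examples
#' pr <- simulate_paired_recording(synapse_params(), modulation_scenario(),
#'                                 pair_protocol(n_sweeps = 5), seed = 1)
#' pr$sweeps
#' @export
simulate_paired_recording <- function(syn = synapse_params(),
                                      mod = modulation_scenario(),
                                      protocol = pair_protocol(),
                                      seed = 1L, pair_id = "pair_1",
                                      holding = holding_model(),
                                      access_step = NULL) {
  stopifnot(inherits(syn, "synapse_params"),
            inherits(mod, "modulation_scenario"),
            inherits(protocol, "pair_protocol"))
  validate_synapse_params(syn)
  set.seed(as.integer(seed))

  ns <- protocol$n_sweeps
  dt <- 1 / protocol$sampling_rate
  len <- round(protocol$sweep_duration / dt)
  t_ms <- (seq_len(len) - 1) * dt
  t_sweep <- (seq_len(ns) - 1) * protocol$sweep_period
  wash <- if (is.na(mod$washout_time)) Inf else mod$washout_time
  epoch <- dplyr::case_when(t_sweep < mod$onset_time ~ "baseline",
                            t_sweep < wash ~ "agonist",
                            TRUE ~ "washout")
  in_mod <- epoch == "agonist"

  p_eff <- rep(syn$release_prob_baseline, ns)
  q_eff <- rep(syn$quantal_amp, ns)
  if (mod$mechanism %in% c("presynaptic_p_scale", "mixed"))
    p_eff[in_mod] <- pmin(1, p_eff[in_mod] * mod$scale_factor)
  if (mod$mechanism == "postsynaptic_q_scale")
    q_eff[in_mod] <- q_eff[in_mod] * mod$scale_factor
  g_eff <- rep(holding$g_ns, ns)
  if (mod$mechanism %in% c("leak_block", "mixed"))
    g_eff[in_mod] <- g_eff[in_mod] * mod$leak_scale

  # two-pulse binomial release with depression + recovery + facilitation
  k1 <- rbinom(ns, syn$n_sites, p_eff)
  depressed <- rbinom(ns, k1, syn$depression_fraction)
  recovered <- rbinom(ns, depressed,
                      1 - exp(-protocol$interpulse_interval /
                                syn$recovery_time_constant))
  avail2 <- syn$n_sites - depressed + recovered
  p2 <- pmin(1, p_eff * (1 + syn$facilitation_increment))
  k2 <- rbinom(ns, avail2, p2)

  lat1 <- pmax(syn$latency_min, rnorm(ns, syn$latency_mean, syn$latency_sd))
  lat2 <- pmax(syn$latency_min, rnorm(ns, syn$latency_mean, syn$latency_sd))

  stim1 <- protocol$stim1_ms
  stim2 <- stim1 + protocol$interpulse_interval
  ap_delay <- 1 # presynaptic AP peak lags stimulus onset by ~1 ms
  ap1 <- stim1 + ap_delay
  ap2 <- stim2 + ap_delay

  # holding current of each sweep at the clamp potential
  i_hold <- g_eff * (protocol$holding_potential - holding$e_rev_mv)
  tp_on <- protocol$test_pulse_start
  tp_off <- tp_on + protocol$test_pulse_duration

  # latency is defined as AP peak -> EPSC onset, onset being the detectable
  # foot of the EPSC (20 % of peak); the kernel start is shifted accordingly
  t20 <- .epsc_t_frac(syn, 0.2)

  traces <- vector("list", ns)
  for (s in seq_len(ns)) {
    tr <- rep(i_hold[s], len)
    if (k1[s] > 0)
      tr <- tr - k1[s] * q_eff[s] *
        .epsc_shape(t_ms - (ap1 + lat1[s] - t20), syn)
    if (k2[s] > 0)
      tr <- tr - k2[s] * q_eff[s] *
        .epsc_shape(t_ms - (ap2 + lat2[s] - t20), syn)
    if (!is.null(tp_on) && !is.na(tp_on)) {
      tp <- t_ms >= tp_on & t_ms < tp_off
      tr[tp] <- tr[tp] + g_eff[s] * protocol$test_pulse_mv
    }
    if (syn$noise_sd_current > 0)
      tr <- tr + rnorm(len, 0, syn$noise_sd_current)
    traces[[s]] <- tr
  }

  access <- holding$access_start_mohm +
    cumsum(rnorm(ns, 0, holding$access_rw_sd))
  if (!is.null(access_step))
    access[seq_len(ns) >= access_step$sweep] <-
      access[seq_len(ns) >= access_step$sweep] + access_step$delta_mohm

  sweeps <- tibble::tibble(
    sweep = seq_len(ns), time_s = t_sweep, epoch = epoch,
    stim1_ms = stim1, stim2_ms = stim2,
    presyn_ap1_ms = ap1, presyn_ap2_ms = ap2,
    access_mohm = access,
    holding_pa = i_hold + rnorm(ns, 0, holding$noise_sd_pa),
    trace = traces)

  # continuous 1 Hz holding-current monitor
  t_mon <- seq(0, max(t_sweep) + protocol$sweep_period - 1, by = 1)
  g_mon <- rep(holding$g_ns, length(t_mon))
  if (mod$mechanism %in% c("leak_block", "mixed"))
    g_mon[t_mon >= mod$onset_time & t_mon < wash] <-
      holding$g_ns * mod$leak_scale
  hold <- tibble::tibble(
    time_s = t_mon,
    current_pa = g_mon * (protocol$holding_potential - holding$e_rev_mv) +
      rnorm(length(t_mon), 0, holding$noise_sd_pa))

  true_cat <- if (mod$mechanism %in% c("presynaptic_p_scale",
                                       "postsynaptic_q_scale", "mixed")) {
    if (mod$scale_factor > 1) "increase"
    else if (mod$scale_factor < 1) "decrease" else "no_change"
  } else "no_change"

  structure(list(
    sweeps = sweeps,
    holding = hold,
    protocol = protocol,
    pair_id = pair_id,
    holding_model = holding,
    ground_truth = list(synapse = syn, scenario = mod,
                        quanta1 = k1, quanta2 = k2,
                        latency1 = lat1, latency2 = lat2,
                        p_eff = p_eff, q_eff = q_eff, g_eff = g_eff,
                        category = true_cat)),
    class = "paired_recording")
}

# normalized difference-of-exponentials EPSC kernel (peak = 1 at t*)
.epsc_shape <- function(t, syn) {
  y <- numeric(length(t))
  pos <- t > 0
  tp <- t[pos]
  raw <- exp(-tp / syn$decay_tau) - exp(-tp / syn$rise_tau)
  tstar <- log(syn$decay_tau / syn$rise_tau) *
    syn$rise_tau * syn$decay_tau / (syn$decay_tau - syn$rise_tau)
  peak <- exp(-tstar / syn$decay_tau) - exp(-tstar / syn$rise_tau)
  y[pos] <- raw / peak
  y
}

# time after kernel start at which the normalized EPSC reaches `frac` of peak
.epsc_t_frac <- function(syn, frac) {
  tstar <- log(syn$decay_tau / syn$rise_tau) *
    syn$rise_tau * syn$decay_tau / (syn$decay_tau - syn$rise_tau)
  tt <- seq(0, tstar, length.out = 2000)
  y <- .epsc_shape(tt, syn)
  stats::approx(y[-1], tt[-1], xout = frac, ties = "ordered")$y
}

#' Postsynaptic leak model for voltage-clamp observables
#'
#' Describes the conductance a voltage-clamped interneuron presents to the
#' amplifier: a leak of `g_ns` nS reversing at `e_rev_mv` (a potassium-like
#' leak), holding-current noise, and a slowly drifting access resistance.
#'
#' @param g_ns nS leak conductance (sets input resistance `1000/g_ns` MOhm).
#' @param e_rev_mv mV reversal of the modulable leak.
#' @param noise_sd_pa pA; holding-current measurement noise.
#' @param access_start_mohm MOhm; initial access resistance.
#' @param access_rw_sd MOhm; per-sweep SD of the access random walk.
#' @return A list of class `holding_model`.
#' @export
holding_model <- function(g_ns = 13, e_rev_mv = -90, noise_sd_pa = 3,
                          access_start_mohm = 25, access_rw_sd = 0.15) {
  stopifnot(g_ns > 0, noise_sd_pa >= 0)
  structure(list(g_ns = g_ns, e_rev_mv = e_rev_mv,
                 noise_sd_pa = noise_sd_pa,
                 access_start_mohm = access_start_mohm,
                 access_rw_sd = access_rw_sd),
            class = "holding_model")
}

#' @export
print.paired_recording <- function(x, ...) {
  cat(sprintf("<paired_recording> %s: %d sweeps (%s), IPI %g ms\n",
              x$pair_id, nrow(x$sweeps),
              paste(sprintf("%s: %d", names(table(x$sweeps$epoch)),
                            as.integer(table(x$sweeps$epoch))),
                    collapse = ", "),
              x$protocol$interpulse_interval))
  invisible(x)
}
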
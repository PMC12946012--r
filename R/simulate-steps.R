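#' Simulate a current-step recording
#'
#' Integrates the adaptive exponential integrate-and-fire model (with sag
#' conductance and stylized spike waveform; see [neuron_params()]) for every
#' step of the protocol and returns the voltage sweeps as a tibble with one
#' row per sweep.
#'
#' @param params a [neuron_params()] object.
#' @param protocol a [step_protocol()] object.
#' @param seed integer seed; the recording is bit-reproducible given the seed.
#' @param cell_id identifier stored with the recording.
#' @return A tibble of class `step_recording` with columns `sweep`,
#'   `current_pa`, `n_true_spikes`, and a list-column `trace` of voltage
#'   vectors (mV). Attributes: `cell_id`, `sampling_khz`, `onset_ms`,
#'   `offset_ms`, `params`, `true_spike_onsets`.
#' @examples
#' rec <- simulate_current_steps(neuron_params("FS"), step_protocol(), seed = 1)
#' rec
#' @export
simulate_current_steps <- function(params, protocol = step_protocol(),
                                   seed = 1L, cell_id = "cell_1") {
  stopifnot(inherits(params, "neuron_params"),
            inherits(protocol, "step_protocol"))
  validate_neuron_params(params)
  set.seed(as.integer(seed))

  dt <- 1 / protocol$sampling_rate
  n_pre <- round(protocol$pre_ms / dt)
  n_step <- round(protocol$step_duration / dt)
  n_post <- round(protocol$post_ms / dt)
  n_tot <- n_pre + n_step + n_post
  currents <- protocol$start_current +
    protocol$increment * (seq_len(protocol$n_steps) - 1)

  rise_ms <- params$spike_amplitude * pi / (2 * params$spike_upstroke_gain)
  decay_ms <- (params$spike_amplitude + params$ahp_depth) * pi /
    (2 * params$spike_repolarization_gain)

  sims <- lapply(currents, function(I) {
    i_vec <- c(rep(0, n_pre), rep(I, n_step), rep(0, n_post))
    adex_integrate_cpp(i_vec, dt,
                       params$membrane_capacitance, params$leak_conductance,
                       params$leak_reversal, params$spike_threshold,
                       params$spike_threshold_slope_factor,
                       params$adaptation_increment,
                       params$adaptation_time_constant,
                       params$spike_amplitude, rise_ms, decay_ms,
                       params$ahp_depth,
                       params$sag_conductance, params$sag_time_constant,
                       params$sag_reversal, params$sag_vhalf, params$sag_slope,
                       params$noise_sd)
  })

  out <- tibble::tibble(
    sweep = seq_along(currents),
    current_pa = currents,
    n_true_spikes = vapply(sims, function(s) length(s$spike_onset_ms), 1L),
    trace = lapply(sims, `[[`, "voltage_mv")
  )
  structure(out,
            class = c("step_recording", class(out)),
            cell_id = cell_id,
            sampling_khz = protocol$sampling_rate,
            onset_ms = protocol$pre_ms,
            offset_ms = protocol$pre_ms + protocol$step_duration,
            params = params,
            true_spike_onsets = lapply(sims, `[[`, "spike_onset_ms"))
}

#' Draw a cohort of neuron parameter sets
#'
#' Cell-to-cell variability is modelled as independent multiplicative
#' log-normal jitter on conductances, capacitance and spike-waveform gains,
#' and additive Gaussian jitter on voltages. The dispersion defaults keep the
#' within-class spread of extracted features realistic for a single
#' interneuron archetype per class.
#'
#' @param n number of cells.
#' @param cell_class `"FS"` or `"nonFS"`.
#' @param seed integer seed.
#' @param cv_conductance,cv_capacitance,cv_gain log-normal coefficients of
#'   variation for leak conductance, capacitance, and spike waveform gains.
#' @param sd_el,sd_vt mV; SD of leak reversal and spike threshold jitter.
#' @param sd_amp mV; SD of spike amplitude jitter.
#' @param cv_sag,cv_adapt log-normal CVs of sag conductance and adaptation
#'   increment.
#' @return A list of `n` [neuron_params()] objects.
#' @export
draw_cohort_params <- function(n, cell_class = c("FS", "nonFS"), seed = 1L,
                               cv_conductance = 0.25, cv_capacitance = 0.15,
                               cv_gain = 0.08, sd_el = 2.5, sd_vt = 1.5,
                               sd_amp = 5, cv_sag = 0.3, cv_adapt = 0.3) {
  cell_class <- match.arg(cell_class)
  set.seed(as.integer(seed))
  base <- neuron_params(cell_class)
  rlnorm1 <- function(cv) {
    sdl <- sqrt(log(1 + cv^2))
    exp(rnorm(1, -sdl^2 / 2, sdl)) # mean 1
  }
  lapply(seq_len(n), function(i) {
    p <- base
    p$leak_conductance <- base$leak_conductance * rlnorm1(cv_conductance)
    p$membrane_capacitance <- base$membrane_capacitance * rlnorm1(cv_capacitance)
    p$leak_reversal <- base$leak_reversal + rnorm(1, 0, sd_el)
    p$spike_threshold <- base$spike_threshold + rnorm(1, 0, sd_vt)
    p$spike_upstroke_gain <- base$spike_upstroke_gain * rlnorm1(cv_gain)
    p$spike_repolarization_gain <- base$spike_repolarization_gain * rlnorm1(cv_gain)
    p$spike_amplitude <- base$spike_amplitude + rnorm(1, 0, sd_amp)
    p$sag_conductance <- base$sag_conductance * rlnorm1(cv_sag)
    p$adaptation_increment <- base$adaptation_increment * rlnorm1(cv_adapt)
    validate_neuron_params(p)
    p
  })
}

#' Simulate a cohort of current-step recordings
#'
#' @param n_per_class cells per class.
#' @param classes character vector of classes to simulate.
#' @param protocol a [step_protocol()].
#' @param seed integer seed; per-cell simulation seeds are derived from it.
#' @param ... passed to [draw_cohort_params()].
#' @return A tibble with columns `cell_id`, `cell_class` (ground truth) and a
#'   list-column `recording` of `step_recording` objects.
#' @export
simulate_step_cohort <- function(n_per_class = 20,
                                 classes = c("FS", "nonFS"),
                                 protocol = step_protocol(), seed = 1L, ...) {
  seed <- as.integer(seed)
  out <- purrr::map(seq_along(classes), function(ci) {
    cls <- classes[ci]
    pars <- draw_cohort_params(n_per_class, cls, seed = seed + 1000L * ci, ...)
    purrr::map(seq_len(n_per_class), function(i) {
      id <- sprintf("%s_%02d", cls, i)
      rec <- simulate_current_steps(pars[[i]], protocol,
                                    seed = seed + 1000L * ci + i, cell_id = id)
      tibble::tibble(cell_id = id, cell_class = cls, recording = list(rec))
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  out
}

#' Rheobase by fine-grained current scan
#'
#' Scans injected current in `resolution`-pA increments (independently of the
#' step protocol grid) and returns the smallest current that elicits at least
#' one spike from the model itself.
#'
#' @param params a [neuron_params()] object.
#' @param range_pa length-2 numeric; scan range in pA.
#' @param resolution pA; scan granularity.
#' @param step_duration ms.
#' @param sampling_rate kHz.
#' @return The rheobase in pA, or `NA` if no scanned current spikes.
#' @export
scan_rheobase <- function(params, range_pa = c(0, 400), resolution = 1,
                          step_duration = 800, sampling_rate = 50) {
  proto <- step_protocol(step_duration = step_duration,
                         start_current = range_pa[1],
                         increment = resolution,
                         n_steps = floor(diff(range_pa) / resolution) + 1,
                         sampling_rate = sampling_rate)
  p <- params
  p$noise_sd <- 0
  rec <- simulate_current_steps(p, proto, seed = 1L)
  hit <- which(rec$n_true_spikes > 0 & rec$current_pa > 0)
  if (!length(hit)) return(NA_real_)
  rec$current_pa[hit[1]]
}

#' @export
print.step_recording <- function(x, ...) {
  cat(sprintf("<step_recording> %s: %d sweeps @ %g kHz, step %g-%g ms\n",
              attr(x, "cell_id"), nrow(x), attr(x, "sampling_khz"),
              attr(x, "onset_ms"), attr(x, "offset_ms")))
  NextMethod()
}
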
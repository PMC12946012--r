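#' Measure an evoked EPSC on one sweep
#'
#' The baseline is the mean current over `baseline_ms` before the stimulus;
#' the amplitude is the absolute difference between the baseline and the
#' extremum of the (lightly smoothed) trace in the detection window
#' (`stim + window[1]` to `stim + window[2]` ms), taken in the EPSC polarity
#' (inward, i.e. negative, by default). An event is a failure when the
#' amplitude is below `max(failure_floor, failure_k * noise_sd_estimate)`.
#' Latency is measured from the presynaptic AP peak to the EPSC onset,
#' defined as the first crossing of 20 % of the peak amplitude (linearly
#' interpolated).
#'
#' @param trace numeric current trace (pA).
#' @param sampling_rate kHz.
#' @param stim_ms stimulus time within the sweep (ms).
#' @param noise_sd_estimate pA; baseline current noise SD.
#' @param presyn_ap_ms presynaptic AP peak time (ms); defaults to `stim_ms`.
#' @param window length-2 numeric, ms after the stimulus searched for the
#'   peak.
#' @param baseline_ms ms averaged before the stimulus.
#' @param polarity `-1` for inward (downward) EPSCs, `+1` for outward.
#' @param failure_floor,failure_k failure threshold `max(floor, k * noise)`.
#' @param onset_frac fraction of the peak defining the onset crossing.
#' @param smooth_ms boxcar width applied before peak search.
#' @return A one-row tibble: `amplitude` (pA, positive magnitude), `latency`
#'   (ms, `NA` for failures), `is_failure`, `baseline_pa`, `peak_ms`,
#'   `valid` (`FALSE` when the window is truncated; such events must be
#'   excluded).
#' @examples
#' syn <- synapse_params(noise_sd_current = 0)
#' pr <- simulate_paired_recording(syn, protocol = pair_protocol(n_sweeps = 1),
#'                                 seed = 1)
#' measure_epsc(pr$sweeps$trace[[1]], 25, stim_ms = 20,
#'              noise_sd_estimate = 0, presyn_ap_ms = 21)
#' @export
measure_epsc <- function(trace, sampling_rate, stim_ms,
                         noise_sd_estimate, presyn_ap_ms = stim_ms,
                         window = c(0.5, 10), baseline_ms = 5,
                         polarity = -1, failure_floor = 5, failure_k = 3,
                         onset_frac = 0.2, smooth_ms = 0.2) {
  dt <- 1 / sampling_rate
  sm <- .boxcar(trace, max(1L, round(smooth_ms / dt)))
  v <- .measure_epsc_vec(trace, sm, dt, stim_ms, noise_sd_estimate,
                         presyn_ap_ms, window, baseline_ms, polarity,
                         failure_floor, failure_k, onset_frac)
  tibble::tibble(amplitude = v[1], latency = v[2],
                 is_failure = if (is.na(v[3])) NA else v[3] > 0,
                 baseline_pa = v[4], peak_ms = v[5], valid = v[6] > 0)
}

# numeric core: c(amplitude, latency, is_failure, baseline, peak_ms, valid)
.measure_epsc_vec <- function(trace, sm, dt, stim_ms, noise_sd_estimate,
                              presyn_ap_ms, window, baseline_ms, polarity,
                              failure_floor, failure_k, onset_frac) {
  n <- length(trace)
  i_stim <- round(stim_ms / dt) + 1L
  i_lo <- round((stim_ms + window[1]) / dt) + 1L
  i_hi <- round((stim_ms + window[2]) / dt) + 1L
  i_base <- round((stim_ms - baseline_ms) / dt) + 1L
  if (i_base < 1 || i_hi > n || i_lo >= i_hi)
    return(c(NA_real_, NA_real_, NA_real_, NA_real_, NA_real_, 0))

  baseline <- mean(trace[i_base:(i_stim - 1L)])
  seg <- sm[i_lo:i_hi]
  dev <- polarity * (seg - baseline)       # positive in the EPSC direction
  i_pk <- which.max(dev)
  amplitude <- max(dev[i_pk], 0)
  thresh <- max(failure_floor, failure_k * noise_sd_estimate)
  is_failure <- amplitude < thresh

  latency <- NA_real_
  peak_ms <- (i_lo + i_pk - 2L) * dt
  if (!is_failure) {
    # onset: first sustained crossing of onset_frac * amplitude between
    # stimulus and peak, on the raw trace (smoothing would advance the
    # crossing; single-sample noise excursions are ignored)
    level <- baseline + polarity * onset_frac * amplitude
    a <- i_stim; b <- i_lo + i_pk - 1L
    onset_ms <- .sustained_crossing(trace, a, b, level,
                                    rising = polarity > 0, dt = dt,
                                    hold = max(1L, round(0.12 / dt)))
    if (!is.na(onset_ms)) latency <- onset_ms - presyn_ap_ms
  }
  c(amplitude, latency, as.numeric(is_failure), baseline, peak_ms, 1)
}

#' Measure both EPSCs on every sweep of a paired recording
#'
#' @param recording a `paired_recording`.
#' @param noise_sd_estimate pA; when `NULL`, estimated as the SD of the
#'   5 ms pre-stimulus baseline across sweeps.
#' @param ... passed to [measure_epsc()].
#' @return A tibble of EPSC events: `sweep`, `pulse` (1 or 2), `epoch`,
#'   `time_s`, `amplitude`, `latency`, `is_failure`, `valid`.
#' @export
measure_connection <- function(recording, noise_sd_estimate = NULL, ...) {
  stopifnot(inherits(recording, "paired_recording"))
  sw <- recording$sweeps
  sr <- recording$protocol$sampling_rate
  if (is.null(noise_sd_estimate)) {
    dt <- 1 / sr
    idx <- seq(round((sw$stim1_ms[1] - 5) / dt) + 1, round(sw$stim1_ms[1] / dt))
    noise_sd_estimate <- mean(vapply(sw$trace, function(tr) sd(tr[idx]), 1))
  }
  args <- list(...)
  window <- args$window %||% c(0.5, 10)
  baseline_ms <- args$baseline_ms %||% 5
  polarity <- args$polarity %||% -1
  failure_floor <- args$failure_floor %||% 5
  failure_k <- args$failure_k %||% 3
  onset_frac <- args$onset_frac %||% 0.2
  smooth_ms <- args$smooth_ms %||% 0.2
  dt <- 1 / sr
  w <- max(1L, round(smooth_ms / dt))

  m <- matrix(NA_real_, 2L * nrow(sw), 6L)
  for (s in seq_len(nrow(sw))) {
    tr <- sw$trace[[s]]
    sm <- .boxcar(tr, w)
    m[2L * s - 1L, ] <- .measure_epsc_vec(
      tr, sm, dt, sw$stim1_ms[s], noise_sd_estimate, sw$presyn_ap1_ms[s],
      window, baseline_ms, polarity, failure_floor, failure_k, onset_frac)
    m[2L * s, ] <- .measure_epsc_vec(
      tr, sm, dt, sw$stim2_ms[s], noise_sd_estimate, sw$presyn_ap2_ms[s],
      window, baseline_ms, polarity, failure_floor, failure_k, onset_frac)
  }
  tibble::tibble(
    sweep = rep(sw$sweep, each = 2L),
    pulse = rep(1:2, nrow(sw)),
    epoch = rep(sw$epoch, each = 2L),
    time_s = rep(sw$time_s, each = 2L),
    amplitude = m[, 1], latency = m[, 2],
    is_failure = m[, 3] > 0, baseline_pa = m[, 4],
    peak_ms = m[, 5], valid = m[, 6] > 0)
}

#' Paired-pulse ratio of one sweep
#'
#' Second EPSC amplitude divided by the first. Undefined (`NA`) when either
#' event is a failure or invalid.
#'
#' @param first,second one-row tibbles from [measure_epsc()] (or lists with
#'   `amplitude` and `is_failure`).
#' @return The ratio, or `NA_real_`.
#' @examples
#' ppr(list(amplitude = 50, is_failure = FALSE, valid = TRUE),
#'     list(amplitude = 75, is_failure = FALSE, valid = TRUE))
#' @export
ppr <- function(first, second) {
  if (!isTRUE(first$valid) || !isTRUE(second$valid)) return(NA_real_)
  if (isTRUE(first$is_failure) || isTRUE(second$is_failure)) return(NA_real_)
  second$amplitude / first$amplitude
}

#' Access-resistance quality control
#'
#' A recording is excluded when the access resistance rises more than
#' `threshold` (default 25 %) above its value at the start of the baseline;
#' exactly 25 % is still included. An empty series flags the recording as
#' unmonitored and keeps it, with a warning.
#'
#' @param recording a `paired_recording` (or anything with
#'   `sweeps$access_mohm`).
#' @param threshold fractional increase tolerated.
#' @return A one-row tibble: `include`, `max_increase`, `reason`.
#' @export
qc_access <- function(recording, threshold = 0.25) {
  series <- recording$sweeps$access_mohm
  series <- series[!is.na(series)]
  if (!length(series)) {
    warning("access resistance unmonitored; recording kept", call. = FALSE)
    return(tibble::tibble(include = TRUE, max_increase = NA_real_,
                          reason = "unmonitored"))
  }
  inc <- max(series) / series[1] - 1
  tibble::tibble(include = inc <= threshold, max_increase = inc,
                 reason = ifelse(inc <= threshold, "ok",
                                 "access_increase_gt_25pct"))
}

#' Analysis epochs relative to agonist wash-in
#'
#' The default windows compare 200 s of baseline immediately before wash-in
#' with the 60-260 s window after it (the agonist window starts 1 min after
#' wash-in so the bath concentration has equilibrated).
#'
#' @param onset_s wash-in time (s of experiment time).
#' @param baseline_window,agonist_window length-2 numerics, s relative to
#'   onset.
#' @return A tibble with columns `epoch`, `start_s`, `end_s`.
#' @export
analysis_epochs <- function(onset_s, baseline_window = c(-200, 0),
                            agonist_window = c(60, 260)) {
  tibble::tibble(
    epoch = c("baseline", "agonist"),
    start_s = onset_s + c(baseline_window[1], agonist_window[1]),
    end_s = onset_s + c(baseline_window[2], agonist_window[2]))
}

#' Categorize the modulation of one connection
#'
#' Compares sweep-wise first-pulse EPSC amplitudes (failures excluded)
#' between the baseline and agonist windows with a two-sided Mann-Whitney
#' test. The connection is categorized as `increase`/`decrease` when
#' p < `alpha` and the agonist mean is higher/lower, `no_change` otherwise,
#' and `indeterminate` when either window has fewer than `min_events`
#' non-failure amplitudes. Also reports per-epoch paired-pulse ratio (mean
#' of sweep ratios), failure rate (over all valid sweeps, failures
#' included), latency, the normalized change
#' `(mean_agonist - mean_baseline) / mean_baseline`, `delta_ppr`
#' (agonist - baseline) and its Mann-Whitney p-value.
#'
#' @param events tibble from [measure_connection()].
#' @param epochs tibble from [analysis_epochs()] (or any `epoch`,
#'   `start_s`, `end_s` table with `baseline` and `agonist` rows).
#' @param alpha significance level.
#' @param min_events minimum non-failure first-pulse amplitudes per window.
#' @param pair_id identifier copied into the summary.
#' @return A one-row tibble (`connection_summary`).
#' @export
categorize_connection <- function(events, epochs, alpha = 0.05,
                                  min_events = 10, pair_id = "pair_1") {
  stopifnot(all(c("baseline", "agonist") %in% epochs$epoch))
  ev <- events[events$valid, ]
  ev$win <- NA_character_
  for (k in seq_len(nrow(epochs))) {
    sel <- ev$time_s >= epochs$start_s[k] & ev$time_s < epochs$end_s[k]
    ev$win[sel] <- epochs$epoch[k]
  }
  ev <- ev[!is.na(ev$win), ]

  first <- ev[ev$pulse == 1L, ]
  amp <- function(w) first$amplitude[first$win == w & !first$is_failure]
  fr <- function(w) mean(first$is_failure[first$win == w])
  lat <- function(w) first$latency[first$win == w & !first$is_failure]

  # sweep-wise PPR within each window (excluded sweeps counted)
  pp <- ev |>
    dplyr::group_by(.data$sweep, .data$win) |>
    dplyr::summarise(ppr = if (any(.data$is_failure[.data$pulse == 1L]) ||
                                any(.data$is_failure[.data$pulse == 2L]))
                             NA_real_
                           else .data$amplitude[.data$pulse == 2L] /
                                .data$amplitude[.data$pulse == 1L],
                     .groups = "drop")
  ppr_vals <- function(w) pp$ppr[pp$win == w & !is.na(pp$ppr)]

  a_b <- amp("baseline"); a_a <- amp("agonist")
  n_excluded_ppr <- sum(is.na(pp$ppr))

  if (length(a_b) < min_events || length(a_a) < min_events) {
    return(tibble::tibble(
      pair_id = pair_id, category = "indeterminate",
      reason = "insufficient_events",
      n_baseline = length(a_b), n_agonist = length(a_a),
      mean_baseline = mean(a_b), mean_agonist = mean(a_a),
      sd_baseline = sd(a_b), sd_agonist = sd(a_a),
      p_value = NA_real_, normalized_change = NA_real_,
      ppr_baseline = mean(ppr_vals("baseline")),
      ppr_agonist = mean(ppr_vals("agonist")),
      delta_ppr = NA_real_, delta_ppr_p = NA_real_,
      failure_rate_baseline = fr("baseline"),
      failure_rate_agonist = fr("agonist"),
      latency_baseline = mean(lat("baseline")),
      latency_sd_baseline = sd(lat("baseline")),
      latency_agonist = mean(lat("agonist")),
      ppr_sweeps_excluded = n_excluded_ppr))
  }

  mw <- mann_whitney(a_b, a_a)
  mb <- mean(a_b); ma <- mean(a_a)
  category <- if (mw$p_value < alpha) {
    if (ma > mb) "increase" else "decrease"
  } else "no_change"

  ppr_b <- ppr_vals("baseline"); ppr_a <- ppr_vals("agonist")
  dppr_p <- if (length(ppr_b) >= 3 && length(ppr_a) >= 3)
    mann_whitney(ppr_b, ppr_a)$p_value else NA_real_

  tibble::tibble(
    pair_id = pair_id, category = category, reason = "ok",
    n_baseline = length(a_b), n_agonist = length(a_a),
    mean_baseline = mb, mean_agonist = ma,
    sd_baseline = sd(a_b), sd_agonist = sd(a_a),
    p_value = mw$p_value,
    normalized_change = (ma - mb) / mb,
    ppr_baseline = mean(ppr_b), ppr_agonist = mean(ppr_a),
    delta_ppr = mean(ppr_a) - mean(ppr_b), delta_ppr_p = dppr_p,
    failure_rate_baseline = fr("baseline"),
    failure_rate_agonist = fr("agonist"),
    latency_baseline = mean(lat("baseline")),
    latency_sd_baseline = sd(lat("baseline")),
    latency_agonist = mean(lat("agonist")),
    ppr_sweeps_excluded = n_excluded_ppr)
}

# first upward (or downward) crossing of `level` between indices a and b that
# stays beyond the level for `hold` samples; linearly interpolated time (ms)
.sustained_crossing <- function(trace, a, b, level, rising, dt, hold = 3L) {
  if (b <= a) return(NA_real_)
  seg <- if (rising) trace[a:b] else -trace[a:b]
  lev <- if (rising) level else -level
  n <- length(seg)
  idx <- which(seg[-1] >= lev & seg[-n] < lev)
  for (i in idx) {
    upto <- min(n, i + hold)
    if (all(seg[(i + 1):upto] >= lev)) {
      v1 <- seg[i]; v2 <- seg[i + 1]
      frac <- if (v2 == v1) 0 else (lev - v1) / (v2 - v1)
      return(((a + i - 1) - 1 + frac) * dt)
    }
  }
  NA_real_
}

#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Exact p-value when both groups have at most `exact_max` observations and
#' there are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param x,y numeric vectors.
#' @param exact_max largest group size for which the exact distribution is
#'   used.
#' @return A list with `statistic` (U of the first sample) and `p_value`.
#' @export
mann_whitney <- function(x, y, exact_max = 8) {
  exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !anyDuplicated(c(x, y))
  ht <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  p <- ht$p.value
  # fully tied data degenerates the normal approximation; report p = 1
  if (!is.finite(p)) p <- 1
  list(statistic = unname(ht$statistic), p_value = p)
}
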
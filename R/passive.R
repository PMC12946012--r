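#' Passive membrane features from a current-step recording
#'
#' * `RMP`: mean pre-stimulus voltage across sweeps (mV).
#' * `tau`: membrane time constant (ms), from a single-exponential fit to the
#'   onset of each hyperpolarizing step (first `fit_window` ms, excluding the
#'   first `fit_skip` ms of pipette transient), averaged across steps.
#' * `Rin`: input resistance (MOhm), mean over hyperpolarizing steps of
#'   steady-state deflection / injected current.
#' * `sag_ratio`: `(V_min - V_ss) / (V_min - V_baseline)` on the -100 pA
#'   sweep; 0 means no sag. The trace is lightly smoothed (`smooth_ms`
#'   boxcar) before taking the minimum so the estimate is not dominated by
#'   the noise floor.
#'
#' Steady state is the mean of the last `ss_window` ms of the step.
#'
#' @param recording a `step_recording`.
#' @param fit_skip,fit_window,ss_window,smooth_ms analysis windows in ms.
#' @param sag_current pA; the step on which sag is measured.
#' @param detail also return per-hyperpolarizing-step columns
#'   (`tau_<I>pA`, `sag_<I>pA`).
#' @return A one-row tibble: `RMP`, `tau`, `Rin`, `sag_ratio`, plus
#'   `tau_fit_failures` (number of non-converged step fits) and, with
#'   `detail = TRUE`, the per-step columns.
#' @export
passive_features <- function(recording, fit_skip = 2, fit_window = 100,
                             ss_window = 100, smooth_ms = 2,
                             sag_current = -100, detail = FALSE) {
  sr <- attr(recording, "sampling_khz")
  on_ms <- attr(recording, "onset_ms")
  off_ms <- attr(recording, "offset_ms")
  dt <- 1 / sr
  i_on <- round(on_ms / dt)
  i_off <- round(off_ms / dt)

  pre_mean <- function(tr) mean(tr[seq_len(max(1, i_on - 1))])
  rmp <- mean(vapply(recording$trace, pre_mean, 1))

  hyp <- which(recording$current_pa < 0)
  if (!length(hyp)) {
    return(tibble::tibble(RMP = rmp, tau = NA_real_, Rin = NA_real_,
                          sag_ratio = NA_real_, tau_fit_failures = NA_integer_))
  }

  ss_idx <- seq(i_off - round(ss_window / dt) + 1, i_off)
  taus <- rins <- rep(NA_real_, length(hyp))
  fails <- 0L
  for (k in seq_along(hyp)) {
    s <- hyp[k]
    tr <- recording$trace[[s]]
    base <- pre_mean(tr)
    vss <- mean(tr[ss_idx])
    rins[k] <- 1000 * (vss - base) / recording$current_pa[s] # mV/pA -> MOhm
    fit_idx <- seq(i_on + round(fit_skip / dt), i_on + round(fit_window / dt))
    tt <- (fit_idx - i_on) * dt
    vv <- tr[fit_idx]
    # crude starting tau: time to cover 63% of the onset-to-steady-state drop
    drop63 <- vv[1] + 0.632 * (vss - vv[1])
    i63 <- which(vv <= drop63)[1]
    start_tau <- if (is.na(i63) || i63 < 2) 10 else tt[i63]
    fit <- tryCatch(
      nls(vv ~ a + b * exp(-tt / tau), algorithm = "port",
          start = list(a = vss, b = vv[1] - vss, tau = start_tau),
          lower = c(a = -Inf, b = -Inf, tau = 0.1),
          upper = c(a = Inf, b = Inf, tau = fit_window)),
      error = function(e) NULL)
    tau_k <- if (is.null(fit)) NA_real_ else coef(fit)[["tau"]]
    # a tau pinned at the window bound means the step is too small/noisy to fit
    if (is.null(fit) || !is.finite(tau_k) || tau_k >= 0.95 * fit_window) {
      fails <- fails + 1L
    } else taus[k] <- tau_k
  }

  sag_of <- function(s) {
    tr <- .boxcar(recording$trace[[s]], max(1L, round(smooth_ms / dt)))
    base <- pre_mean(tr)
    vss <- mean(tr[ss_idx])
    vmin <- min(tr[i_on:i_off])
    denom <- vmin - base
    if (abs(denom) < 1e-9) NA_real_ else (vmin - vss) / denom
  }
  s100 <- which(recording$current_pa == sag_current)
  sag <- if (length(s100)) sag_of(s100[1]) else NA_real_

  out <- tibble::tibble(RMP = rmp, tau = mean(taus, na.rm = TRUE),
                        Rin = mean(rins), sag_ratio = sag,
                        tau_fit_failures = fails)
  if (detail) {
    for (k in seq_along(hyp)) {
      I <- recording$current_pa[hyp[k]]
      out[[sprintf("tau_%dpA", abs(I))]] <- taus[k]
      out[[sprintf("sag_%dpA", abs(I))]] <- sag_of(hyp[k])
    }
  }
  out
}

.boxcar <- function(x, w) {
  if (w <= 1) return(x)
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2)) |>
    (\(y) { y[is.na(y)] <- x[is.na(y)]; y })()
}

#' Firing features from a current-step recording
#'
#' * `rheobase`: current of the first sweep (ascending) with at least one AP.
#' * `isi_accommodation_norm`: for every sweep with >= 3 APs, mean interspike
#'   interval divided by the AP count; averaged over qualifying sweeps
#'   (ms/spike).
#' * `ap_amp_adaptation`: mean of consecutive AP amplitude differences
#'   (later minus earlier; mV/spike), over sweeps with >= 2 APs.
#' * plus supporting features used by the default registry (f-I slope, ISI
#'   CV, first-spike latency at rheobase, maximal spike count, spike
#'   frequency adaptation ratio, median ISI).
#'
#' @param recording a `step_recording`.
#' @param aps completed AP events from [detect_recording_aps()].
#' @return A one-row tibble of firing features (`NA` where undefined, e.g. no
#'   spiking sweep).
#' @export
firing_features <- function(recording, aps) {
  on_ms <- attr(recording, "onset_ms")
  dur_s <- (attr(recording, "offset_ms") - on_ms) / 1000
  if (is.null(aps) || !nrow(aps)) {
    return(tibble::tibble(rheobase = NA_real_,
                          isi_accommodation_norm = NA_real_,
                          ap_amp_adaptation = NA_real_,
                          threshold_voltage = NA_real_, ahp_depth = NA_real_,
                          f_i_slope = NA_real_, f_i_intercept = NA_real_,
                          isi_cv = NA_real_,
                          first_spike_latency = NA_real_,
                          max_spike_count = 0,
                          adaptation_ratio = NA_real_, median_isi = NA_real_,
                          isi_mean_top = NA_real_,
                          max_inst_rate = NA_real_))
  }
  counts <- dplyr::count(aps, .data$sweep)
  spiking <- counts$sweep
  dep <- recording$sweep[recording$current_pa > 0]
  rheo_sweep <- suppressWarnings(min(intersect(spiking, dep)))
  rheobase <- if (is.finite(rheo_sweep))
    recording$current_pa[recording$sweep == rheo_sweep] else NA_real_

  per_sweep <- aps |>
    dplyr::group_by(.data$sweep) |>
    dplyr::summarise(
      n_ap = dplyr::n(),
      mean_isi = if (dplyr::n() >= 2) mean(diff(.data$peak_time)) else NA_real_,
      isi_cv = if (dplyr::n() >= 3) sd(diff(.data$peak_time)) / mean(diff(.data$peak_time)) else NA_real_,
      adapt_ratio = if (dplyr::n() >= 3) {
        isis <- diff(.data$peak_time); isis[length(isis)] / isis[1]
      } else NA_real_,
      amp_adapt = if (dplyr::n() >= 2) mean(diff(.data$amplitude)) else NA_real_,
      first_latency = min(.data$peak_time) - on_ms,
      .groups = "drop")

  q3 <- per_sweep[per_sweep$n_ap >= 3, ]
  isi_acc <- if (nrow(q3)) mean(q3$mean_isi / q3$n_ap) else NA_real_
  amp_adapt <- if (any(per_sweep$n_ap >= 2))
    mean(per_sweep$amp_adapt[per_sweep$n_ap >= 2]) else NA_real_

  # f-I slope: spikes/s per pA over spiking depolarizing sweeps
  fi <- dplyr::left_join(
    tibble::tibble(sweep = dep,
                   current_pa = recording$current_pa[match(dep, recording$sweep)]),
    counts, by = "sweep")
  fi$n[is.na(fi$n)] <- 0L
  fi_fit <- if (sum(fi$n > 0) >= 2)
    coef(lm((fi$n / dur_s) ~ fi$current_pa)) else c(NA_real_, NA_real_)
  f_i_slope <- unname(fi_fit[2])
  f_i_intercept <- unname(fi_fit[1])
  min_isi <- suppressWarnings(
    min(aps |> dplyr::group_by(.data$sweep) |>
          dplyr::summarise(m = if (dplyr::n() >= 2)
            min(diff(.data$peak_time)) else NA_real_, .groups = "drop") |>
          dplyr::pull(.data$m), na.rm = TRUE))
  max_inst_rate <- if (is.finite(min_isi)) 1000 / min_isi else NA_real_

  top <- per_sweep[which.max(per_sweep$n_ap), ]
  rheo_lat <- if (is.finite(rheo_sweep))
    per_sweep$first_latency[per_sweep$sweep == rheo_sweep] else NA_real_

  tibble::tibble(
    rheobase = rheobase,
    isi_accommodation_norm = isi_acc,
    ap_amp_adaptation = amp_adapt,
    threshold_voltage = mean(aps$threshold_voltage),
    ahp_depth = mean(aps$ahp_depth, na.rm = TRUE),
    f_i_slope = f_i_slope,
    f_i_intercept = f_i_intercept,
    isi_cv = top$isi_cv,
    first_spike_latency = rheo_lat,
    max_spike_count = max(per_sweep$n_ap),
    adaptation_ratio = top$adapt_ratio,
    median_isi = median(per_sweep$mean_isi, na.rm = TRUE),
    isi_mean_top = top$mean_isi,
    max_inst_rate = max_inst_rate
  )
}
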
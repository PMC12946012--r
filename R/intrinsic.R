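#' Holding-current time course and per-cell modulation category
#'
#' Subtracts the baseline (pre-onset) mean from the holding-current series,
#' averages it in `bin_width`-second bins, and tests pre- versus post-onset
#' bin means with a two-sided Mann-Whitney test. The cell is categorized as
#' `decrease`/`increase` (p < `alpha` and sign of the post-onset mean) or
#' `no_change`; fewer than `min_bins` bins on either side gives
#' `indeterminate`.
#'
#' @param holding tibble with `time_s` and `current_pa` (e.g.
#'   `recording$holding`), or a `paired_recording`.
#' @param onset s; agonist wash-in time.
#' @param bin_width s.
#' @param alpha significance level.
#' @param min_bins minimum bins per side.
#' @return A list with `bins` (tibble: `bin_center_s`, `mean_pa`, `n`,
#'   `phase`) and `summary` (one-row tibble: `baseline_mean_pa`,
#'   `post_mean_pa`, `delta_pa`, `p_value`, `category`).
#' @examples
#' pr <- simulate_paired_recording(
#'   mod = modulation_scenario("leak_block", onset_time = 150,
#'                             leak_scale = 0.8),
#'   protocol = pair_protocol(n_sweeps = 30), seed = 1)
#' holding_course(pr, onset = 150)$summary
#' @export
holding_course <- function(holding, onset, bin_width = 10, alpha = 0.05,
                           min_bins = 3) {
  if (inherits(holding, "paired_recording")) holding <- holding$holding
  stopifnot(all(c("time_s", "current_pa") %in% names(holding)))
  base_mean <- mean(holding$current_pa[holding$time_s < onset])
  h <- dplyr::mutate(holding,
                     centered_pa = .data$current_pa - base_mean,
                     bin = floor((.data$time_s - onset) / bin_width))
  bins <- h |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(bin_center_s = onset + (.data$bin[1] + 0.5) * bin_width,
                     mean_pa = mean(.data$centered_pa), n = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(phase = ifelse(.data$bin < 0, "baseline", "post"))

  pre <- bins$mean_pa[bins$phase == "baseline"]
  post <- bins$mean_pa[bins$phase == "post"]
  if (length(pre) < min_bins || length(post) < min_bins) {
    summary <- tibble::tibble(baseline_mean_pa = base_mean,
                              post_mean_pa = base_mean + mean(post),
                              delta_pa = mean(post), p_value = NA_real_,
                              category = "indeterminate")
  } else {
    p <- mann_whitney(pre, post)$p_value
    delta <- mean(post)
    category <- if (p < alpha) {
      if (delta < 0) "decrease" else "increase"
    } else "no_change"
    summary <- tibble::tibble(baseline_mean_pa = base_mean,
                              post_mean_pa = base_mean + delta,
                              delta_pa = delta, p_value = p,
                              category = category)
  }
  list(bins = bins[, c("bin_center_s", "mean_pa", "n", "phase")],
       summary = summary)
}

#' Input-resistance change from per-sweep test pulses
#'
#' Re-measures the input resistance on every sweep from the deflection of
#' the test pulse (`Rin = dV / dI`), compares the baseline and agonist
#' sweep-wise estimates with a two-sided Mann-Whitney test, and categorizes
#' the cell.
#'
#' @param recording a `paired_recording` whose protocol includes a test
#'   pulse.
#' @param onset s; defaults to the scenario onset in the ground truth.
#' @param alpha significance level.
#' @return A one-row tibble: `rin_baseline`, `rin_agonist`, `ratio`,
#'   `p_value`, `category` (`increase`/`decrease`/`no_change`), `n_baseline`,
#'   `n_agonist`. Errors if the protocol has no test pulse.
#' @export
rin_change <- function(recording, onset = NULL, alpha = 0.05) {
  stopifnot(inherits(recording, "paired_recording"))
  proto <- recording$protocol
  if (is.null(proto$test_pulse_start) || is.na(proto$test_pulse_start))
    stop("recording has no input-resistance test pulses", call. = FALSE)
  if (is.null(onset)) onset <- recording$ground_truth$scenario$onset_time

  dt <- 1 / proto$sampling_rate
  on_i <- round(proto$test_pulse_start / dt) + 1L
  off_i <- round((proto$test_pulse_start + proto$test_pulse_duration) / dt)
  skip <- round(2 / dt)  # settle
  base_i <- seq(max(1L, on_i - round(5 / dt)), on_i - 1L)

  rins <- vapply(recording$sweeps$trace, function(tr) {
    di <- mean(tr[(on_i + skip):off_i]) - mean(tr[base_i])
    1000 * proto$test_pulse_mv / di  # mV/pA -> MOhm
  }, 1)

  pre <- rins[recording$sweeps$time_s < onset]
  post <- rins[recording$sweeps$time_s >= onset]
  if (length(pre) < 3 || length(post) < 3)
    return(tibble::tibble(rin_baseline = mean(pre), rin_agonist = mean(post),
                          ratio = NA_real_, p_value = NA_real_,
                          category = "indeterminate",
                          n_baseline = length(pre), n_agonist = length(post)))
  p <- mann_whitney(pre, post)$p_value
  rb <- mean(pre); ra <- mean(post)
  category <- if (p < alpha) {
    if (ra > rb) "increase" else "decrease"
  } else "no_change"
  tibble::tibble(rin_baseline = rb, rin_agonist = ra, ratio = ra / rb,
                 p_value = p, category = category,
                 n_baseline = length(pre), n_agonist = length(post))
}

#' Intrinsic-property summary of one cell
#'
#' Combines [holding_course()] and [rin_change()] into the per-cell summary
#' used for population tables and pie-chart style category counts.
#'
#' @param recording a `paired_recording`.
#' @param onset s; agonist wash-in (defaults to the scenario onset).
#' @param cell_class optional FS / non-FS label carried through.
#' @return A one-row tibble with holding and Rin statistics and categories.
#' @export
intrinsic_summary <- function(recording, onset = NULL, cell_class = NA) {
  if (is.null(onset)) onset <- recording$ground_truth$scenario$onset_time
  hc <- holding_course(recording, onset)
  rc <- rin_change(recording, onset)
  tibble::tibble(
    cell_id = recording$pair_id, cell_class = cell_class,
    holding_baseline_pa = hc$summary$baseline_mean_pa,
    holding_delta_pa = hc$summary$delta_pa,
    holding_p = hc$summary$p_value,
    holding_category = hc$summary$category,
    rin_baseline = rc$rin_baseline, rin_agonist = rc$rin_agonist,
    rin_ratio = rc$ratio, rin_p = rc$p_value, rin_category = rc$category)
}
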
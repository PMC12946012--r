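#' Detect action potentials in a voltage trace
#'
#' An AP is detected where dV/dt crosses `dvdt_threshold` upward and the
#' voltage subsequently reaches a local maximum above `peak_criterion`. The
#' threshold point of the event is the time of the dV/dt criterion crossing.
#' Double detections within `merge_ms` of each other are merged (the first
#' is kept).
#'
#' @param trace numeric voltage trace (mV).
#' @param sampling_rate kHz.
#' @param dvdt_threshold mV/ms; detection criterion on the rising slope.
#' @param peak_criterion mV; minimum voltage the subsequent peak must exceed.
#' @param merge_ms ms; refractory merge window for double detections.
#' @return A tibble with one row per AP: `threshold_index`, `threshold_time`,
#'   `threshold_voltage`, `peak_index`, `peak_time`, `peak_voltage` (times in
#'   ms from trace start, indices 1-based).
#' @examples
#' rec <- simulate_current_steps(neuron_params("FS"), step_protocol(), seed = 1)
#' detect_aps(rec$trace[[15]], attr(rec, "sampling_khz"))
#' @export
detect_aps <- function(trace, sampling_rate, dvdt_threshold = 20,
                       peak_criterion = -10, merge_ms = 1) {
  if (!all(is.finite(trace))) stop("trace contains non-finite values", call. = FALSE)
  if (sampling_rate < 2 * dvdt_threshold / 10)
    stop("sampling rate too low to resolve the dV/dt criterion", call. = FALSE)
  dt <- 1 / sampling_rate
  n <- length(trace)
  empty <- tibble::tibble(threshold_index = integer(), threshold_time = numeric(),
                          threshold_voltage = numeric(), peak_index = integer(),
                          peak_time = numeric(), peak_voltage = numeric())
  if (n < 3) return(empty)

  deriv <- diff(trace) / dt           # deriv[i] = slope from sample i to i+1
  up <- which(deriv[-1] >= dvdt_threshold & deriv[-length(deriv)] < dvdt_threshold) + 1L
  if (!length(up)) return(empty)

  thr_idx <- integer(0)
  pk_idx <- integer(0)
  last_time <- -Inf
  last_peak <- -1L
  for (i0 in up) {
    t0 <- (i0 - 1) * dt
    if (t0 - last_time < merge_ms) next
    # walk forward to the first local maximum
    j <- i0
    while (j < n - 1 && trace[j + 1] >= trace[j]) j <- j + 1L
    if (j >= n - 1) next                       # truncated rise, no peak
    if (trace[j] <= peak_criterion) next       # sub-criterion bump
    if (j == last_peak) next                   # same peak re-detected
    thr_idx <- c(thr_idx, i0)
    pk_idx <- c(pk_idx, j)
    last_time <- t0
    last_peak <- j
  }
  if (!length(thr_idx)) return(empty)
  tibble::tibble(
    threshold_index = thr_idx,
    threshold_time = (thr_idx - 1) * dt,
    threshold_voltage = trace[thr_idx],
    peak_index = pk_idx,
    peak_time = (pk_idx - 1) * dt,
    peak_voltage = trace[pk_idx])
}

#' Action-potential shape features
#'
#' Completes a detected event with amplitude, half-width and dV/dt extrema.
#' The half-width is measured between linearly interpolated crossings of
#' `threshold_voltage + amplitude / 2` on the rising and decaying phases;
#' upstroke and downstroke are the extrema of the discrete derivative within
#' the spike window (threshold to the recrossing of the threshold voltage,
#' bounded by the next event).
#'
#' @param trace numeric voltage trace (mV).
#' @param event one row of the tibble returned by [detect_aps()].
#' @param sampling_rate kHz.
#' @param next_threshold_index first index of the next event (bounds the
#'   spike window), or `NA`.
#' @return A one-row tibble: `threshold_time`, `peak_time`,
#'   `threshold_voltage`, `peak_voltage`, `amplitude`, `half_width`,
#'   `max_upstroke`, `min_downstroke`, `ahp_depth`. `half_width` is `NA` if
#'   the decay never recrosses the half level before the window ends.
#' @export
ap_shape_features <- function(trace, event, sampling_rate,
                              next_threshold_index = NA_integer_) {
  v <- .ap_shape_vec(trace, event$threshold_index, event$peak_index,
                     1 / sampling_rate, next_threshold_index)
  tibble::tibble(
    threshold_time = v[1], peak_time = v[2], threshold_voltage = v[3],
    peak_voltage = v[4], amplitude = v[5], half_width = v[6],
    max_upstroke = v[7], min_downstroke = v[8], ahp_depth = v[9])
}

# linearly interpolated time (ms) at which `trace` crosses `level` between
# indices a and b; rising = crossing from below, otherwise from above
.interp_crossing <- function(trace, a, b, level, rising, dt) {
  if (b <= a) return(NA_real_)
  seg <- trace[a:b]
  idx <- if (rising) which(seg[-1] >= level & seg[-length(seg)] < level)
         else which(seg[-1] <= level & seg[-length(seg)] > level)
  if (!length(idx)) return(NA_real_)
  i <- idx[1]
  v1 <- seg[i]; v2 <- seg[i + 1]
  frac <- if (v2 == v1) 0 else (level - v1) / (v2 - v1)
  ((a + i - 1) - 1 + frac) * dt
}

#' Detect and characterize APs on every sweep of a recording
#'
#' @param recording a `step_recording`.
#' @param ... passed to [detect_aps()].
#' @return A tibble of completed AP events with a `sweep` column.
#' @export
detect_recording_aps <- function(recording, ...) {
  sr <- attr(recording, "sampling_khz")
  dt <- 1 / sr
  cols <- c("threshold_time", "peak_time", "threshold_voltage",
            "peak_voltage", "amplitude", "half_width", "max_upstroke",
            "min_downstroke", "ahp_depth")
  rows <- lapply(seq_len(nrow(recording)), function(s) {
    tr <- recording$trace[[s]]
    ev <- detect_aps(tr, sr, ...)
    ne <- nrow(ev)
    if (!ne) return(NULL)
    m <- matrix(NA_real_, ne, length(cols) + 1L)
    for (k in seq_len(ne)) {
      nxt <- if (k < ne) ev$threshold_index[k + 1] else NA_integer_
      m[k, ] <- c(s, .ap_shape_vec(tr, ev$threshold_index[k],
                                   ev$peak_index[k], dt, nxt))
    }
    m
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- as.data.frame(matrix(numeric(0), 0, length(cols) + 1L))
    names(out) <- c("sweep", cols)
    return(tibble::as_tibble(out))
  }
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("sweep", cols)
  tibble::as_tibble(out)
}

# fast path of ap_shape_features: returns the numeric feature vector
.ap_shape_vec <- function(trace, i0, ip, dt, next_threshold_index) {
  n <- length(trace)
  thr_v <- trace[i0]
  pk_v <- trace[ip]
  amplitude <- pk_v - thr_v
  half <- thr_v + amplitude / 2
  end <- if (is.na(next_threshold_index)) n else
    min(n, next_threshold_index - 1L)
  j <- ip
  while (j < end && trace[j] > thr_v) j <- j + 1L
  win_end <- j
  cross_up <- .interp_crossing(trace, i0, ip, half, rising = TRUE, dt = dt)
  cross_down <- .interp_crossing(trace, ip, win_end, half, rising = FALSE,
                                 dt = dt)
  hw <- if (is.na(cross_up) || is.na(cross_down)) NA_real_ else
    cross_down - cross_up
  dv <- diff(trace[i0:win_end]) / dt
  ahp_end <- min(end, ip + round(10 / dt))
  c((i0 - 1) * dt, (ip - 1) * dt, thr_v, pk_v, amplitude, hw,
    if (length(dv)) max(dv) else NA_real_,
    if (length(dv)) min(dv) else NA_real_,
    if (ahp_end > ip) thr_v - min(trace[ip:ahp_end]) else NA_real_)
}
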
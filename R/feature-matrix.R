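#' The default electrophysiological feature registry
#'
#' Names the features extracted per cell: the 11 core features reported for
#' FS / non-FS comparisons (RMP, tau, Rin, sag ratio, rheobase, AP
#' half-width, AP amplitude, max upstroke, min downstroke, normalized ISI
#' accommodation, AP amplitude adaptation), supporting scalar features
#' (threshold voltage, AHP depth, f-I slope and intercept, ISI statistics,
#' AP waveform timing), and per-step features (spike count per depolarizing
#' step; steady-state deflection, fitted time constant and sag ratio per
#' hyperpolarizing step). With the default 21-step protocol this yields 55
#' features.
#'
#' @param protocol a [step_protocol()]; determines the per-step entries.
#' @return Character vector of feature names.
#' @examples
#' length(default_feature_registry()) # 55
#' @export
default_feature_registry <- function(protocol = step_protocol()) {
  currents <- protocol$start_current +
    protocol$increment * (seq_len(protocol$n_steps) - 1)
  dep <- currents[currents > 0]
  hyp <- currents[currents < 0]
  c(.mandatory_features,
    "threshold_voltage", "ahp_depth", "f_i_slope", "f_i_intercept",
    "isi_cv", "first_spike_latency", "max_spike_count", "adaptation_ratio",
    "median_isi", "isi_mean_top", "max_inst_rate", "rebound_depol",
    "ap_rise_time", "ap_peak_voltage", "ap_amplitude_cv",
    sprintf("spike_count_%dpA", dep),
    sprintf("deflection_%dpA", abs(hyp)),
    sprintf("tau_%dpA", abs(hyp)),
    sprintf("sag_%dpA", abs(hyp[hyp != min(hyp)])))
}

.mandatory_features <- c("RMP", "tau", "Rin", "sag_ratio", "rheobase",
                         "ap_halfwidth", "ap_amplitude", "max_upstroke",
                         "min_downstroke", "isi_accommodation_norm",
                         "ap_amp_adaptation")

#' Extract the full feature vector of one cell
#'
#' Runs AP detection, AP shape, passive and firing feature extraction on a
#' current-step recording and assembles the registry features into a one-row
#' tibble. Features that cannot be computed (e.g. no spiking sweep) are `NA`.
#'
#' @param recording a `step_recording`.
#' @param registry character vector of feature names to keep (and order by).
#' @return A one-row tibble with `cell_id` plus one column per registry
#'   feature.
#' @export
extract_features <- function(recording, registry = default_feature_registry()) {
  aps <- detect_recording_aps(recording)
  pas <- passive_features(recording, detail = TRUE)
  fir <- firing_features(recording, aps)
  sr <- attr(recording, "sampling_khz")
  dt <- 1 / sr
  on_ms <- attr(recording, "onset_ms")
  off_ms <- attr(recording, "offset_ms")
  i_on <- round(on_ms / dt); i_off <- round(off_ms / dt)

  shape <- if (!is.null(aps) && nrow(aps)) {
    tibble::tibble(ap_halfwidth = mean(aps$half_width, na.rm = TRUE),
                   ap_amplitude = mean(aps$amplitude),
                   max_upstroke = mean(aps$max_upstroke, na.rm = TRUE),
                   min_downstroke = mean(aps$min_downstroke, na.rm = TRUE),
                   ap_rise_time = mean(aps$peak_time - aps$threshold_time),
                   ap_peak_voltage = mean(aps$peak_voltage),
                   ap_amplitude_cv = sd(aps$amplitude) /
                     mean(aps$amplitude))
  } else {
    tibble::tibble(ap_halfwidth = NA_real_, ap_amplitude = NA_real_,
                   max_upstroke = NA_real_, min_downstroke = NA_real_,
                   ap_rise_time = NA_real_, ap_peak_voltage = NA_real_,
                   ap_amplitude_cv = NA_real_)
  }

  # per-step features
  counts <- if (!is.null(aps) && nrow(aps)) dplyr::count(aps, .data$sweep)
            else tibble::tibble(sweep = integer(), n = integer())
  per_step <- list()
  for (s in seq_len(nrow(recording))) {
    I <- recording$current_pa[s]
    tr <- recording$trace[[s]]
    if (I > 0) {
      n_ap <- counts$n[match(s, counts$sweep)]
      n_ap <- if (is.na(n_ap)) 0L else n_ap
      per_step[[sprintf("spike_count_%dpA", I)]] <- n_ap
    } else if (I < 0) {
      base <- mean(tr[seq_len(max(1, i_on - 1))])
      vss <- mean(tr[seq(i_off - round(100 / dt) + 1, i_off)])
      per_step[[sprintf("deflection_%dpA", abs(I))]] <- vss - base
    }
  }
  # rebound depolarization after the strongest hyperpolarizing step
  s_min <- which.min(recording$current_pa)
  reb <- NA_real_
  if (recording$current_pa[s_min] < 0) {
    tr <- recording$trace[[s_min]]
    base <- mean(tr[seq_len(max(1, i_on - 1))])
    post <- tr[seq(i_off + 1, length(tr))]
    reb <- max(.boxcar(post, max(1L, round(2 / dt)))) - base
  }

  row <- dplyr::bind_cols(
    tibble::tibble(cell_id = attr(recording, "cell_id")),
    pas[, setdiff(names(pas), "tau_fit_failures")], shape,
    fir, tibble::tibble(rebound_depol = reb),
    tibble::as_tibble(per_step))
  missing <- setdiff(registry, names(row))
  for (m in missing) row[[m]] <- NA_real_
  row[, c("cell_id", registry)]
}

#' Extract features for a simulated cohort
#'
#' @param cohort tibble from [simulate_step_cohort()] (columns `cell_id`,
#'   `recording`, optionally `cell_class`).
#' @param registry feature registry.
#' @return A tibble of cells x features (plus `cell_id` and, when present,
#'   `cell_class`).
#' @export
extract_cohort_features <- function(cohort,
                                    registry = default_feature_registry()) {
  feats <- purrr::map(cohort$recording, extract_features, registry = registry) |>
    purrr::list_rbind()
  if ("cell_class" %in% names(cohort))
    feats <- dplyr::mutate(feats, cell_class = cohort$cell_class,
                           .after = "cell_id")
  feats
}

#' Build the scaled feature matrix
#'
#' Range-scales every registry feature to [0, 1] across cells. Constant
#' columns are set to 0.5 and flagged; missing values are imputed with the
#' column median (before scaling) and flagged; a column with no finite value
#' raises an error naming the feature.
#'
#' @param features tibble from [extract_cohort_features()] (needs `cell_id`
#'   plus feature columns).
#' @param registry feature names to include, in order.
#' @return An object of class `feature_matrix`: a list with `raw` and
#'   `scaled` cell-by-feature tibbles, `bounds` (per-feature min/max and
#'   constant flag) and `flags` (cell/feature imputation records).
#' @examples
#' f <- tibble::tibble(cell_id = c("a", "b", "c"), x = c(2, 4, 6))
#' build_feature_matrix(f, registry = "x")$scaled$x
#' @export
build_feature_matrix <- function(features,
                                 registry = default_feature_registry()) {
  stopifnot(nrow(features) >= 2)
  missing_cols <- setdiff(registry, names(features))
  if (length(missing_cols))
    stop("features table lacks registry columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  raw <- features[, c("cell_id", registry)]
  scaled <- raw
  bounds <- list(); flags <- list()
  for (f in registry) {
    x <- raw[[f]]
    finite <- is.finite(x)
    if (!any(finite))
      stop(sprintf("feature '%s' has no finite values", f), call. = FALSE)
    if (!all(finite)) {
      med <- median(x[finite])
      flags[[length(flags) + 1L]] <- tibble::tibble(
        cell_id = raw$cell_id[!finite], feature = f, reason = "imputed_median")
      x[!finite] <- med
    }
    lo <- min(x); hi <- max(x)
    constant <- (hi - lo) < 1e-12
    scaled[[f]] <- if (constant) rep(0.5, length(x)) else (x - lo) / (hi - lo)
    if (constant)
      flags[[length(flags) + 1L]] <- tibble::tibble(
        cell_id = NA_character_, feature = f, reason = "constant_column")
    bounds[[length(bounds) + 1L]] <- tibble::tibble(
      feature = f, min = lo, max = hi, constant = constant)
  }
  structure(list(raw = raw, scaled = scaled,
                 bounds = purrr::list_rbind(bounds),
                 flags = if (length(flags)) purrr::list_rbind(flags) else
                   tibble::tibble(cell_id = character(), feature = character(),
                                  reason = character())),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d cells x %d features (%d flags)\n",
              nrow(x$scaled), ncol(x$scaled) - 1L, nrow(x$flags)))
  invisible(x)
}
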
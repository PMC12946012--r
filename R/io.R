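#' Write a simulated dataset to a plain-text sweep container
#'
#' The on-disk layout is a directory tree of CSV sweep tables plus JSON
#' metadata sidecars:
#' \preformatted{
#'   <dir>/manifest.json            sampling rates, units, protocol, seeds
#'   <dir>/cells/<id>/sweeps.csv    long table: sweep, current_pa, time_ms,
#'                                  voltage_mv
#'   <dir>/pairs/<id>/sweeps.csv    long table: sweep, time_ms, current_pa
#'   <dir>/pairs/<id>/sweep_table.csv  per-sweep metadata (epoch, stimulus
#'                                  times, access resistance, holding)
#'   <dir>/pairs/<id>/holding.csv   1 Hz holding-current monitor
#'   <dir>/ground_truth.json        generator parameters per cell/connection
#' }
#' All quantities keep the package units (mV, ms, pA, MOhm, s).
#'
#' @param cells tibble from [simulate_step_cohort()], or `NULL`.
#' @param pairs list of `paired_recording` objects, or `NULL`.
#' @param dir output directory (created if needed).
#' @param overwrite allow writing into an existing directory.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(cells = NULL, pairs = NULL, dir,
                          overwrite = FALSE) {
  if (dir.exists(dir) && !overwrite &&
      length(list.files(dir)))
    stop("output directory exists and is not empty", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt <- list()

  if (!is.null(cells)) {
    for (i in seq_len(nrow(cells))) {
      rec <- cells$recording[[i]]
      id <- cells$cell_id[i]
      d <- file.path(dir, "cells", id)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      dt <- 1 / attr(rec, "sampling_khz")
      long <- purrr::map(seq_len(nrow(rec)), function(s) {
        tr <- rec$trace[[s]]
        data.frame(sweep = s, current_pa = rec$current_pa[s],
                   time_ms = (seq_along(tr) - 1) * dt, voltage_mv = tr)
      }) |> purrr::list_rbind()
      utils::write.csv(long, file.path(d, "sweeps.csv"), row.names = FALSE)
      gt$cells[[id]] <- c(list(cell_class = cells$cell_class[i]),
                          unclass(attr(rec, "params")))
    }
  }

  if (!is.null(pairs)) {
    for (rec in pairs) {
      id <- rec$pair_id
      d <- file.path(dir, "pairs", id)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      dt <- 1 / rec$protocol$sampling_rate
      long <- purrr::map(seq_len(nrow(rec$sweeps)), function(s) {
        tr <- rec$sweeps$trace[[s]]
        data.frame(sweep = s, time_ms = (seq_along(tr) - 1) * dt,
                   current_pa = tr)
      }) |> purrr::list_rbind()
      utils::write.csv(long, file.path(d, "sweeps.csv"), row.names = FALSE)
      meta <- rec$sweeps[, setdiff(names(rec$sweeps), "trace")]
      utils::write.csv(meta, file.path(d, "sweep_table.csv"),
                       row.names = FALSE)
      utils::write.csv(rec$holding, file.path(d, "holding.csv"),
                       row.names = FALSE)
      gt$pairs[[id]] <- list(
        synapse = unclass(rec$ground_truth$synapse),
        scenario = unclass(rec$ground_truth$scenario),
        quanta1 = rec$ground_truth$quanta1,
        quanta2 = rec$ground_truth$quanta2,
        category = rec$ground_truth$category,
        protocol = unclass(rec$protocol))
    }
  }

  manifest <- list(
    format = "pairephys-sweeps-v1",
    units = list(voltage = "mV", current = "pA", time_trace = "ms",
                 time_experiment = "s", resistance = "MOhm"),
    n_cells = if (is.null(cells)) 0L else nrow(cells),
    n_pairs = if (is.null(pairs)) 0L else length(pairs))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a current-step recording from the sweep container
#'
#' @param dir dataset directory written by [write_dataset()].
#' @param cell_id cell identifier (subdirectory of `cells/`).
#' @param sampling_rate kHz; inferred from the time column when `NULL`.
#' @param onset_ms,offset_ms step window; inferred from the ground-truth
#'   sidecar protocol when absent, else required.
#' @return A `step_recording` tibble.
#' @export
read_step_recording <- function(dir, cell_id, sampling_rate = NULL,
                                onset_ms = 100, offset_ms = 900) {
  f <- file.path(dir, "cells", cell_id, "sweeps.csv")
  if (!file.exists(f)) stop("no such cell: ", cell_id, call. = FALSE)
  long <- utils::read.csv(f)
  if (is.null(sampling_rate))
    sampling_rate <- 1 / diff(long$time_ms[1:2])
  sweeps <- split(long, long$sweep)
  out <- tibble::tibble(
    sweep = as.integer(names(sweeps)),
    current_pa = unname(vapply(sweeps, function(s) s$current_pa[1], 1)),
    n_true_spikes = NA_integer_,
    trace = unname(lapply(sweeps, function(s) s$voltage_mv)))
  structure(out, class = c("step_recording", class(out)),
            cell_id = cell_id, sampling_khz = sampling_rate,
            onset_ms = onset_ms, offset_ms = offset_ms, params = NULL,
            true_spike_onsets = NULL)
}

#' Read a paired recording from the sweep container
#'
#' @param dir dataset directory written by [write_dataset()].
#' @param pair_id pair identifier (subdirectory of `pairs/`).
#' @return A `paired_recording` (without ground truth unless the sidecar is
#'   present).
#' @export
read_paired_recording <- function(dir, pair_id) {
  d <- file.path(dir, "pairs", pair_id)
  if (!dir.exists(d)) stop("no such pair: ", pair_id, call. = FALSE)
  long <- utils::read.csv(file.path(d, "sweeps.csv"))
  meta <- utils::read.csv(file.path(d, "sweep_table.csv"))
  holding <- utils::read.csv(file.path(d, "holding.csv"))
  sr <- 1 / diff(long$time_ms[1:2])
  traces <- lapply(split(long, long$sweep), function(s) s$current_pa)
  sweeps <- tibble::as_tibble(meta)
  sweeps$trace <- traces[as.character(sweeps$sweep)]

  gt_file <- file.path(dir, "ground_truth.json")
  gt <- NULL
  proto <- NULL
  if (file.exists(gt_file)) {
    all_gt <- jsonlite::read_json(gt_file, simplifyVector = TRUE)
    g <- all_gt$pairs[[pair_id]]
    if (!is.null(g)) {
      proto <- do.call(pair_protocol, g$protocol[
        intersect(names(g$protocol), names(formals(pair_protocol)))])
      gt <- list(synapse = do.call(synapse_params, g$synapse[
                   intersect(names(g$synapse), names(formals(synapse_params)))]),
                 scenario = do.call(modulation_scenario, g$scenario),
                 quanta1 = g$quanta1, quanta2 = g$quanta2,
                 category = g$category)
    }
  }
  if (is.null(proto)) {
    dur <- max(long$time_ms) + 1 / sr
    proto <- pair_protocol(
      n_sweeps = nrow(sweeps), sampling_rate = sr, sweep_duration = dur,
      stim1_ms = sweeps$stim1_ms[1],
      interpulse_interval = sweeps$stim2_ms[1] - sweeps$stim1_ms[1],
      sweep_period = if (nrow(sweeps) > 1) diff(sweeps$time_s[1:2]) else 10)
  }
  structure(list(sweeps = sweeps, holding = tibble::as_tibble(holding),
                 protocol = proto, pair_id = pair_id,
                 holding_model = NULL, ground_truth = gt),
            class = "paired_recording")
}

#' Write a feature matrix as CSV plus JSON metadata
#'
#' @param fm a [build_feature_matrix()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_feature_matrix <- function(fm, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(fm$raw, file.path(dir, "features_raw.csv"),
                   row.names = FALSE)
  utils::write.csv(fm$scaled, file.path(dir, "features_scaled.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(bounds = fm$bounds, flags = fm$flags),
    file.path(dir, "features_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
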
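#' Default pipeline configuration
#'
#' A fully serializable list of seeds, cohort sizes, protocol settings and
#' analysis parameters. A run is reproducible bit for bit from its
#' configuration.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param n_cells_per_class cells per class for the classification arm.
#' @param n_connections connections per modulation scenario.
#' @param n_sweeps_per_epoch paired-recording sweeps per analysis epoch.
#' @param n_intrinsic cells in the intrinsic (leak-block) arm.
#' @param scenarios named list of modulation scenarios for the synaptic arm;
#'   each entry has `mechanism` and `scale_factor`.
#' @param leak_scale leak-conductance factor of the intrinsic arm.
#' @param alpha significance level used throughout.
#' @return A list of class `run_config`.
#' @export
default_config <- function(seed = 1L, n_cells_per_class = 10,
                           n_connections = 6, n_sweeps_per_epoch = 20,
                           n_intrinsic = 6,
                           scenarios = list(
                             presynaptic = list(
                               mechanism = "presynaptic_p_scale",
                               scale_factor = 1.3),
                             postsynaptic = list(
                               mechanism = "postsynaptic_q_scale",
                               scale_factor = 1.3)),
                           leak_scale = 0.8, alpha = 0.05) {
  structure(list(seed = as.integer(seed),
                 seeds = list(simulation = as.integer(seed),
                              embedding = 42L, clustering = 42L),
                 n_cells_per_class = n_cells_per_class,
                 n_connections = n_connections,
                 n_sweeps_per_epoch = n_sweeps_per_epoch,
                 n_intrinsic = n_intrinsic,
                 scenarios = scenarios,
                 leak_scale = leak_scale,
                 alpha = alpha),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> features -> classify -> synapse -> intrinsic and
#' returns all result tables; optionally writes them (CSV + JSON) to a
#' directory.
#'
#' @param config a [default_config()] list.
#' @param out_dir optional output directory for the report bundle.
#' @return A list of class `pipeline_result`: `classification` (labels +
#'   silhouette), `group_comparison`, `connections` (per-scenario
#'   summaries), `cohort_stats`, `correlations`, `intrinsic`
#'   (per-cell summaries and category counts), `config`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config") || is.list(config))

  # --- classification arm -------------------------------------------------
  stage <- "features/classify"
  res <- tryCatch({
    coh <- simulate_step_cohort(config$n_cells_per_class,
                                seed = config$seeds$simulation)
    feats <- extract_cohort_features(coh)
    fm <- build_feature_matrix(feats)
    cls <- classify_cells(fm, seed = config$seeds$embedding)
    cmp <- compare_groups(feats, cls)
    list(feats = feats, fm = fm, cls = cls, cmp = cmp)
  }, error = function(e)
    stop("stage ", stage, " failed: ", conditionMessage(e), call. = FALSE))

  # --- synaptic arm -------------------------------------------------------
  stage <- "synapse"
  syn_res <- tryCatch({
    if (config$n_connections < 1) {
      warning("no connections configured; synapse stage skipped",
              call. = FALSE)
      list(connections = tibble::tibble(), cohort_stats = NULL,
           correlations = NULL)
    } else {
      sums <- purrr::imap(config$scenarios, function(sc, nm) {
        out <- simulate_connection_cohort(
          config$n_connections, mechanism = sc$mechanism,
          scale_factor = sc$scale_factor,
          n_sweeps_per_epoch = config$n_sweeps_per_epoch,
          seed = config$seeds$simulation +
            1000L * match(nm, names(config$scenarios)),
          alpha = config$alpha)
        dplyr::mutate(out, scenario = nm, .before = 1)
      }) |> purrr::list_rbind()
      stats <- cohort_statistics(sums, grouping = "scenario")
      cors <- tryCatch(
        purrr::imap(split(sums, sums$scenario), function(g, nm)
          dplyr::mutate(correlate_predictors(g), scenario = nm,
                        .before = 1)) |> purrr::list_rbind(),
        error = function(e) NULL)
      list(connections = sums, cohort_stats = stats, correlations = cors)
    }
  }, error = function(e)
    stop("stage ", stage, " failed: ", conditionMessage(e), call. = FALSE))

  # --- intrinsic arm ------------------------------------------------------
  stage <- "intrinsic"
  intr <- tryCatch({
    if (config$n_intrinsic < 1) list(cells = tibble::tibble(), counts = NULL)
    else {
      onset <- config$n_sweeps_per_epoch * 10
      proto <- pair_protocol(n_sweeps = 2 * config$n_sweeps_per_epoch)
      cells <- purrr::map(seq_len(config$n_intrinsic), function(i) {
        rec <- simulate_paired_recording(
          synapse_params(),
          modulation_scenario("leak_block", onset_time = onset,
                              leak_scale = config$leak_scale),
          proto, seed = config$seeds$simulation + 5000L + i,
          pair_id = sprintf("intr_%02d", i))
        intrinsic_summary(rec, onset = onset)
      }) |> purrr::list_rbind()
      counts <- cells |>
        dplyr::count(.data$holding_category, name = "n_holding") |>
        dplyr::rename(category = "holding_category") |>
        dplyr::full_join(
          cells |> dplyr::count(.data$rin_category, name = "n_rin") |>
            dplyr::rename(category = "rin_category"),
          by = "category")
      list(cells = cells, counts = counts)
    }
  }, error = function(e)
    stop("stage ", stage, " failed: ", conditionMessage(e), call. = FALSE))

  out <- structure(list(
    classification = res$cls,
    group_comparison = res$cmp,
    features = res$feats,
    connections = syn_res$connections,
    cohort_stats = syn_res$cohort_stats,
    correlations = syn_res$correlations,
    intrinsic = intr,
    config = config), class = "pipeline_result")

  if (!is.null(out_dir)) write_pipeline_result(out, out_dir)
  out
}

#' Write a pipeline result bundle
#'
#' CSV tables plus a machine-readable `results.json` and a short plain-text
#' summary.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) if (!is.null(x) && nrow(x))
    utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  w(as.data.frame(result$classification), "classification.csv")
  w(result$group_comparison, "group_comparison.csv")
  w(result$connections, "connections.csv")
  if (!is.null(result$cohort_stats)) {
    w(result$cohort_stats$categories, "category_percentages.csv")
    w(result$cohort_stats$tests, "cohort_tests.csv")
  }
  w(result$correlations, "correlations.csv")
  w(result$intrinsic$cells, "intrinsic_cells.csv")

  json <- list(
    config = unclass(result$config),
    classification = as.data.frame(result$classification),
    mean_silhouette = attr(result$classification, "mean_silhouette"),
    group_comparison = result$group_comparison,
    connections = result$connections,
    category_percentages =
      if (!is.null(result$cohort_stats)) result$cohort_stats$categories,
    cohort_tests = if (!is.null(result$cohort_stats))
      result$cohort_stats$tests,
    correlations = result$correlations,
    intrinsic = result$intrinsic$cells)
  jsonlite::write_json(json, file.path(dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  summary_lines <- c(
    "pairephys pipeline summary",
    sprintf("seed: %d", result$config$seed),
    sprintf("cells: %d per class, mean silhouette %.3f",
            result$config$n_cells_per_class,
            attr(result$classification, "mean_silhouette")),
    sprintf("connections: %d", nrow(result$connections)),
    sprintf("intrinsic cells: %d",
            if (is.null(result$intrinsic$cells)) 0L
            else nrow(result$intrinsic$cells)))
  writeLines(summary_lines, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  classification: %d cells, mean silhouette %.3f\n",
              nrow(x$classification),
              attr(x$classification, "mean_silhouette")))
  cat(sprintf("  connections: %d summaries\n", nrow(x$connections)))
  if (!is.null(x$intrinsic$cells) && nrow(x$intrinsic$cells))
    cat(sprintf("  intrinsic: %d cells\n", nrow(x$intrinsic$cells)))
  invisible(x)
}
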
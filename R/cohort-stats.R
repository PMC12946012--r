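#' Summarize one paired recording end to end
#'
#' Runs access-resistance QC, EPSC measurement and modulation
#' categorization. The analysis windows default to 200 s of baseline before
#' wash-in and 60-260 s after it; for baseline-only recordings (scenario
#' `none` without onset inside the recording) the whole recording is treated
#' as baseline and no category is assigned.
#'
#' @param recording a `paired_recording`.
#' @param onset_s agonist wash-in time; defaults to the scenario onset
#'   stored in the recording's ground truth.
#' @param epochs optional explicit epochs table (overrides `onset_s`).
#' @param ... passed to [categorize_connection()].
#' @return A one-row `connection_summary` tibble with QC columns
#'   (`qc_excluded`, `qc_reason`) prepended.
#' @export
summarize_connection <- function(recording, onset_s = NULL, epochs = NULL,
                                 ...) {
  qc <- qc_access(recording)
  if (is.null(epochs)) {
    if (is.null(onset_s))
      onset_s <- recording$ground_truth$scenario$onset_time
    epochs <- analysis_epochs(onset_s)
  }
  events <- measure_connection(recording)
  out <- categorize_connection(events, epochs, pair_id = recording$pair_id,
                               ...)
  dplyr::bind_cols(
    out[, "pair_id"],
    tibble::tibble(qc_excluded = !qc$include, qc_reason = qc$reason),
    out[, setdiff(names(out), "pair_id")])
}

#' Simulate and summarize a cohort of connections
#'
#' Simulates `n` paired recordings under a common modulation mechanism
#' (with optional heterogeneity in baseline release probability), measures
#' them and returns the per-connection summaries. Used for population-level
#' properties of the release model, e.g. the dissociation between pre- and
#' postsynaptic modulation in the PPR.
#'
#' @param n connections.
#' @param mechanism passed to [modulation_scenario()].
#' @param scale_factor modulation strength.
#' @param n_sweeps_per_epoch sweeps in each of baseline and agonist.
#' @param seed integer; per-connection seeds are derived from it.
#' @param p_range length-2; baseline release probabilities drawn uniformly
#'   from this range (set both ends equal for a homogeneous cohort).
#' @param syn base [synapse_params()]; `release_prob_baseline` is
#'   overwritten per connection.
#' @param ... passed to [summarize_connection()].
#' @return A tibble of connection summaries with the drawn
#'   `release_prob_baseline` and the true category appended.
#' @export
simulate_connection_cohort <- function(n, mechanism = "presynaptic_p_scale",
                                       scale_factor = 1.3,
                                       n_sweeps_per_epoch = 20,
                                       seed = 1L,
                                       p_range = c(0.2, 0.5),
                                       syn = synapse_params(), ...) {
  seed <- as.integer(seed)
  set.seed(seed)
  p_base <- runif(n, p_range[1], p_range[2])
  period <- 10
  onset <- n_sweeps_per_epoch * period
  # sweeps cover baseline (-onset..0) and agonist (onset..onset + window)
  proto <- pair_protocol(n_sweeps = 2 * n_sweeps_per_epoch + 7)
  purrr::map(seq_len(n), function(i) {
    s <- syn
    s$release_prob_baseline <- p_base[i]
    mod <- modulation_scenario(mechanism, scale_factor = scale_factor,
                               onset_time = onset)
    rec <- simulate_paired_recording(
      s, mod, proto, seed = seed + i,
      pair_id = sprintf("%s_%03d", mechanism, i))
    base_win <- c(-n_sweeps_per_epoch * period, 0)
    ag_win <- c(60, 60 + n_sweeps_per_epoch * period)
    out <- summarize_connection(
      rec, epochs = analysis_epochs(onset, baseline_window = base_win,
                                    agonist_window = ag_win), ...)
    out$release_prob_baseline <- p_base[i]
    out$true_category <- rec$ground_truth$category
    out
  }) |> purrr::list_rbind()
}

#' Population statistics over connection summaries
#'
#' Per group: modulation category counts and percentages (rounded to the
#' nearest integer percent), and paired baseline-vs-agonist comparisons of
#' mean EPSC amplitude, PPR and failure rate. Each paired comparison uses a
#' paired t-test when the Shapiro-Wilk test on the paired differences gives
#' p >= 0.05 and the Wilcoxon signed-rank test otherwise; identical pairs
#' (all differences zero) are reported with p = 1 and flagged.
#'
#' @param summaries tibble of connection summaries; QC-excluded and
#'   indeterminate rows are dropped with a message.
#' @param grouping name of the grouping column, or `NULL` for a single
#'   group.
#' @return A list with `categories` (group, category, n, percent) and
#'   `tests` (group, measure, n, mean_baseline, mean_agonist, test, p_value,
#'   zero_diff).
#' @export
cohort_statistics <- function(summaries, grouping = NULL) {
  s <- summaries
  if ("qc_excluded" %in% names(s) && any(s$qc_excluded, na.rm = TRUE)) {
    message(sum(s$qc_excluded), " connection(s) removed by access QC")
    s <- s[!s$qc_excluded, ]
  }
  if ("category" %in% names(s) && any(s$category == "indeterminate")) {
    message(sum(s$category == "indeterminate"),
            " indeterminate connection(s) dropped")
    s <- s[s$category != "indeterminate", ]
  }
  s$.group <- if (is.null(grouping)) "all" else s[[grouping]]

  categories <- s |>
    dplyr::count(.data$.group, .data$category) |>
    dplyr::group_by(.data$.group) |>
    dplyr::mutate(percent = round(100 * .data$n / sum(.data$n))) |>
    dplyr::ungroup() |>
    dplyr::rename(group = ".group")

  paired_one <- function(b, a) {
    ok <- is.finite(b) & is.finite(a)
    b <- b[ok]; a <- a[ok]
    n <- length(b)
    if (n < 3)
      return(tibble::tibble(n = n, mean_baseline = mean(b),
                            mean_agonist = mean(a), test = "none",
                            p_value = NA_real_, zero_diff = FALSE))
    d <- a - b
    if (all(abs(d) < 1e-12))
      return(tibble::tibble(n = n, mean_baseline = mean(b),
                            mean_agonist = mean(a), test = "degenerate",
                            p_value = 1, zero_diff = TRUE))
    sw_p <- tryCatch(shapiro.test(d)$p.value, error = function(e) 0)
    if (sw_p >= 0.05) {
      ht <- t.test(a, b, paired = TRUE)
      tibble::tibble(n = n, mean_baseline = mean(b), mean_agonist = mean(a),
                     test = "paired_t", p_value = ht$p.value,
                     zero_diff = FALSE)
    } else {
      ht <- suppressWarnings(wilcox.test(a, b, paired = TRUE))
      tibble::tibble(n = n, mean_baseline = mean(b), mean_agonist = mean(a),
                     test = "wilcoxon_signed_rank", p_value = ht$p.value,
                     zero_diff = FALSE)
    }
  }

  measures <- list(
    amplitude = c("mean_baseline", "mean_agonist"),
    ppr = c("ppr_baseline", "ppr_agonist"),
    failure_rate = c("failure_rate_baseline", "failure_rate_agonist"))
  tests <- purrr::map(split(s, s$.group), function(g) {
    purrr::imap(measures, function(cols, m) {
      if (!all(cols %in% names(g))) return(NULL)
      dplyr::mutate(paired_one(g[[cols[1]]], g[[cols[2]]]), measure = m,
                    .before = 1)
    }) |> purrr::list_rbind()
  })
  tests <- purrr::imap(tests, function(t, g)
    dplyr::mutate(t, group = g, .before = 1)) |> purrr::list_rbind()

  list(categories = categories, tests = tests)
}

#' Correlate baseline synaptic predictors with the normalized EPSC change
#'
#' Pearson correlation (two-sided) and least-squares line for each of
#' baseline PPR, delta PPR and baseline amplitude against the normalized
#' change `(agonist - baseline) / baseline`. A positive baseline-PPR
#' correlation indicates that synapses with low initial release probability
#' are preferentially strengthened; a negative delta-PPR correlation couples
#' EPSC enhancement with release-probability increases (a presynaptic
#' signature).
#'
#' @param summaries tibble of connection summaries.
#' @param predictors named character vector mapping predictor labels to
#'   summary columns.
#' @param response column name of the response.
#' @return A tibble: `predictor`, `n`, `r`, `p_value`, `slope`, `intercept`.
#' @export
correlate_predictors <- function(summaries,
                                 predictors = c(
                                   baseline_ppr = "ppr_baseline",
                                   delta_ppr = "delta_ppr",
                                   baseline_amplitude = "mean_baseline"),
                                 response = "normalized_change") {
  y_all <- summaries[[response]]
  purrr::imap(predictors, function(col, label) {
    x <- summaries[[col]]; y <- y_all
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3)
      stop("need at least 3 finite connections for predictor ", label,
           call. = FALSE)
    if (var(x) < 1e-14 || var(y) < 1e-14)
      stop("zero-variance predictor or response (", label,
           "): correlation undefined", call. = FALSE)
    ct <- cor.test(x, y, method = "pearson")
    fit <- lm(y ~ x)
    tibble::tibble(predictor = label, n = length(x),
                   r = unname(ct$estimate), p_value = ct$p.value,
                   slope = unname(coef(fit)[2]),
                   intercept = unname(coef(fit)[1]))
  }) |> purrr::list_rbind()
}
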
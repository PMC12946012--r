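make_epsc_sweep <- function(amp = 60, stim = 20, latency = 2, sr = 25,
                            len_ms = 160, noise = 0, baseline = -100,
                            rise = 0.2, decay = 2) {
  t <- seq(0, len_ms - 1 / sr, by = 1 / sr)
  tt <- t - stim - latency
  shape <- ifelse(tt > 0, exp(-tt / decay) - exp(-tt / rise), 0)
  tstar <- log(decay / rise) * rise * decay / (decay - rise)
  shape <- shape / (exp(-tstar / decay) - exp(-tstar / rise))
  baseline - amp * shape + rnorm(length(t), 0, noise)
}

test_that("a noiseless EPSC template is measured at its constructed amplitude", {
  tr <- make_epsc_sweep(amp = 60, latency = 2)
  ev <- measure_epsc(tr, 25, stim_ms = 20, noise_sd_estimate = 0)
  expect_true(ev$valid)
  expect_false(ev$is_failure)
  expect_equal(ev$amplitude, 60, tolerance = 0.01)
  expect_equal(ev$baseline_pa, -100, tolerance = 1e-6)
})

test_that("a flat noisy sweep is a failure and a truncated window is invalid", {
  set.seed(5)
  tr <- rnorm(4000, -100, 2)
  ev <- measure_epsc(tr, 25, stim_ms = 20, noise_sd_estimate = 2)
  expect_true(ev$is_failure)
  ev2 <- measure_epsc(tr, 25, stim_ms = 158, noise_sd_estimate = 2)
  expect_false(ev2$valid)
})

test_that("latency is measured from the presynaptic AP peak to the EPSC onset", {
  tr <- make_epsc_sweep(amp = 60, latency = 3)
  ev <- measure_epsc(tr, 25, stim_ms = 20, noise_sd_estimate = 0,
                     presyn_ap_ms = 20)
  # onset (20 % of peak) sits just after the kernel foot at stim + 3
  expect_gt(ev$latency, 3)
  expect_lt(ev$latency, 3.15)
})

test_that("paired-pulse ratio follows its definition and failure rules", {
  ok <- function(a) list(amplitude = a, is_failure = FALSE, valid = TRUE)
  expect_equal(ppr(ok(50), ok(50)), 1.0)
  expect_equal(ppr(ok(50), ok(75)), 1.5)
  expect_true(is.na(ppr(list(amplitude = 3, is_failure = TRUE, valid = TRUE),
                        ok(50))))
  expect_true(is.na(ppr(ok(50), list(amplitude = 1, is_failure = TRUE,
                                     valid = TRUE))))
})

test_that("access QC excludes > 25 % increases and keeps the boundary", {
  fake <- function(series) list(sweeps = tibble::tibble(access_mohm = series))
  expect_true(qc_access(fake(c(20, 22, 24)))$include)          # 20 %
  expect_false(qc_access(fake(c(20, 23, 26)))$include)         # 30 %
  expect_true(qc_access(fake(c(20, 21, 25)))$include)          # exactly 25 %
  expect_warning(out <- qc_access(fake(numeric(0))), "unmonitored")
  expect_true(out$include)
})

test_that("categorization reproduces constructed normalized changes", {
  mk_events <- function(base_amps, ag_amps) {
    n <- length(base_amps) + length(ag_amps)
    tibble::tibble(
      sweep = rep(seq_len(n), each = 2),
      pulse = rep(1:2, n),
      epoch = NA_character_,
      time_s = rep(c(seq(-195, by = 10, length.out = length(base_amps)),
                     seq(65, by = 10, length.out = length(ag_amps))),
                   each = 2),
      amplitude = rep(c(base_amps, ag_amps), each = 2),
      latency = 1, is_failure = FALSE, valid = TRUE)
  }
  eps <- analysis_epochs(0)
  # identical windows: no change, normalized change 0
  ev <- mk_events(rep(c(99, 100, 101), 7), rep(c(99, 100, 101), 7))
  s <- categorize_connection(ev, eps)
  expect_equal(s$category, "no_change")
  expect_equal(s$normalized_change, 0, tolerance = 1e-9)
  # disjoint 100 vs 130: increase, normalized change 0.30
  set.seed(2)
  ev2 <- mk_events(100 + runif(20, -1, 1), 130 + runif(20, -1, 1))
  s2 <- categorize_connection(ev2, eps)
  expect_equal(s2$category, "increase")
  expect_equal(s2$normalized_change, 0.30, tolerance = 0.01)
  expect_lt(s2$p_value, 0.05)
  # insufficient events
  ev3 <- mk_events(rep(100, 5), rep(130, 5))
  s3 <- categorize_connection(ev3, eps)
  expect_equal(s3$category, "indeterminate")
})

test_that("normalized change is invariant to uniform amplitude rescaling", {
  set.seed(3)
  base <- 80 + rnorm(20, 0, 5); ag <- 100 + rnorm(20, 0, 5)
  mk <- function(f) tibble::tibble(
    sweep = rep(1:40, each = 2), pulse = rep(1:2, 40),
    epoch = NA, time_s = rep(c(seq(-195, by = 10, length.out = 20),
                               seq(65, by = 10, length.out = 20)), each = 2),
    amplitude = rep(c(base, ag) * f, each = 2),
    latency = 1, is_failure = FALSE, valid = TRUE)
  s1 <- categorize_connection(mk(1), analysis_epochs(0))
  s2 <- categorize_connection(mk(7.3), analysis_epochs(0))
  expect_equal(s1$normalized_change, s2$normalized_change, tolerance = 1e-12)
})

test_that("cohort statistics reproduce category percentages and handle degenerate pairs", {
  tab <- published_connection_categories()
  tab$group <- paste(tab$species, tab$cell_class)
  cs <- cohort_statistics(tab, grouping = "group")
  pct <- function(g, cat) {
    r <- cs$categories[cs$categories$group == g &
                         cs$categories$category == cat, ]
    if (nrow(r)) r$percent else 0
  }
  expect_equal(pct("human FS", "increase"), round(100 * 6 / 11))
  expect_equal(pct("human nonFS", "increase"), round(100 * 2 / 13))
  expect_equal(pct("rat FS", "increase"), round(100 * 5 / 14))

  # all-identical paired values: degenerate Wilcoxon handled as p = 1
  s <- tibble::tibble(category = "no_change",
                      mean_baseline = c(50, 60, 70),
                      mean_agonist = c(50, 60, 70),
                      ppr_baseline = 1, ppr_agonist = 1,
                      failure_rate_baseline = 0, failure_rate_agonist = 0)
  cs2 <- cohort_statistics(s)
  amp_row <- cs2$tests[cs2$tests$measure == "amplitude", ]
  expect_equal(amp_row$p_value, 1)
  expect_true(amp_row$zero_diff)
})

test_that("predictor correlations recover exact linear relations and reject degenerate input", {
  s <- tibble::tibble(ppr_baseline = c(1, 2, 3, 4, 5),
                      delta_ppr = c(-0.1, -0.2, -0.3, -0.4, -0.5),
                      mean_baseline = c(10, 20, 30, 40, 50),
                      normalized_change = 2 * c(1, 2, 3, 4, 5))
  ct <- correlate_predictors(s)
  b <- ct[ct$predictor == "baseline_ppr", ]
  expect_equal(b$r, 1, tolerance = 1e-9)
  expect_equal(b$slope, 2, tolerance = 1e-9)
  s2 <- dplyr::mutate(s, normalized_change = 1)
  expect_error(correlate_predictors(s2), "zero-variance")
})

test_that("predictor correlations carry the presynaptic signature on a heterogeneous cohort", {
  # release probabilities up to near saturation: p * 1.3 caps at 1, so
  # high-p (low-PPR) connections strengthen less -> baseline PPR correlates
  # positively with the normalized change, and stronger enhancement couples
  # with larger PPR drops -> delta PPR correlates negatively
  sums <- simulate_connection_cohort(60, "presynaptic_p_scale", 1.3,
                                     n_sweeps_per_epoch = 20, seed = 9,
                                     p_range = c(0.3, 0.95))
  ct <- correlate_predictors(sums)
  expect_gt(ct$r[ct$predictor == "baseline_ppr"], 0)
  expect_lt(ct$r[ct$predictor == "delta_ppr"], 0)
})

test_that("presynaptic and postsynaptic scaling dissociate in the PPR while both increase amplitudes", {
  pre <- simulate_connection_cohort(1, "presynaptic_p_scale", 1.3,
                                    n_sweeps_per_epoch = 60, seed = 5,
                                    p_range = c(0.4, 0.4))
  post <- simulate_connection_cohort(1, "postsynaptic_q_scale", 1.3,
                                     n_sweeps_per_epoch = 60, seed = 5,
                                     p_range = c(0.4, 0.4))
  expect_equal(pre$category, "increase")
  expect_equal(post$category, "increase")
  expect_lt(pre$delta_ppr, 0)
  expect_gt(post$normalized_change, 0.15)
})
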
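test_that("a flat trace contains no APs and a constructed spike is localized exactly", {
  expect_equal(nrow(detect_aps(rep(-65, 5000), 50)), 0)

  # piecewise-linear spike: slope ramps 10 -> 110 mV/ms into an apex at
  # t = 100 ms, then a linear decay
  sr <- 50; dt <- 1 / sr
  t <- seq(0, 200, by = dt)
  v <- rep(-65, length(t))
  ramp <- t >= 99 & t <= 100
  tr <- t[ramp] - 99
  v[ramp] <- -65 + cumsum((10 + 100 * tr) * dt)   # integral of the slope ramp
  apex <- v[which(ramp)[length(which(ramp))]]
  decay <- t > 100 & t <= 101
  v[decay] <- apex - 60 * (t[decay] - 100)
  v[t > 101] <- v[which(decay)[sum(decay)]]
  ev <- detect_aps(v, sr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_time, 100, tolerance = dt)
})

test_that("detection equals the brute-force local-maximum oracle on simulated sweeps", {
  for (cls in c("FS", "nonFS")) {
    rec <- simulate_current_steps(neuron_params(cls), step_protocol(),
                                  seed = 5)
    for (s in seq_len(nrow(rec))) {
      expect_equal(nrow(detect_aps(rec$trace[[s]], 50)),
                   brute_force_spike_count(rec$trace[[s]]),
                   info = sprintf("%s sweep %d", cls, s))
    }
  }
})

test_that("detection refuses a sampling rate too low for the dV/dt criterion", {
  expect_error(detect_aps(rep(-65, 100), sampling_rate = 0.5),
               "sampling rate")
})

test_that("half-width is exact on triangular and Gaussian spikes", {
  sr <- 100; dt <- 1 / sr
  # symmetric triangle: 0.2 ms rise, 0.2 ms decay, 80 mV amplitude
  t <- seq(0, 10, by = dt)
  v <- rep(-65, length(t))
  v <- v + pmax(0, 80 * (1 - abs(t - 5) / 0.2))
  ev <- detect_aps(v, sr)
  sh <- ap_shape_features(v, ev[1, ], sr)
  expect_equal(sh$half_width, 0.2, tolerance = 0.015)

  # Gaussian spike, sd 0.1 ms: FWHM = 2.3548 * sigma
  v2 <- -65 + 100 * exp(-(t - 5)^2 / (2 * 0.1^2))
  ev2 <- detect_aps(v2, sr)
  sh2 <- ap_shape_features(v2, ev2[1, ], sr)
  expect_equal(sh2$half_width, 2.3548 * 0.1, tolerance = 0.01)
})

test_that("half-width is flagged missing when the decay never recrosses the half level", {
  sr <- 100; dt <- 1 / sr
  t <- seq(0, 5, by = dt)
  v <- -65 + ifelse(t < 2, 0, pmin(80, (t - 2) * 200))  # rise, then plateau
  ev <- detect_aps(v, sr)
  expect_equal(nrow(ev), 0)  # no local maximum: nothing detected at all
  # rising then clamped just above half: peak exists, decay does not recross
  v3 <- -65 + pmax(0, 80 * (1 - abs(t - 2.5) / 0.2))
  v3[t > 2.5] <- pmax(v3[t > 2.5], -65 + 50)
  ev3 <- detect_aps(v3, sr)
  sh3 <- ap_shape_features(v3, ev3[1, ], sr)
  expect_true(is.na(sh3$half_width))
})

test_that("passive features recover RC constants on a noiseless cell", {
  rec <- simulate_current_steps(passive_cell(), step_protocol(), seed = 1)
  pf <- passive_features(rec)
  expect_equal(pf$Rin, 100, tolerance = 0.01)
  expect_equal(pf$tau, 10, tolerance = 0.05)
  expect_equal(pf$RMP, -65, tolerance = 1e-6)
  # monotone exponential approach, no sag conductance: sag ratio ~ 0
  expect_lt(abs(pf$sag_ratio), 0.01)
})

test_that("sag ratio matches the value computed from the noiseless trace extrema", {
  p <- neuron_params("nonFS", noise_sd = 0)
  rec <- simulate_current_steps(p, step_protocol(), seed = 1)
  pf <- passive_features(rec)
  tr <- rec$trace[[1]]  # the -100 pA sweep
  sr <- attr(rec, "sampling_khz")
  i_on <- 100 * sr; i_off <- 900 * sr
  base <- mean(tr[1:(i_on - 1)])
  vmin <- min(tr[i_on:i_off])
  vss <- mean(tr[(i_off - 100 * sr + 1):i_off])
  expect_equal(pf$sag_ratio, (vmin - vss) / (vmin - base), tolerance = 0.01)
})

test_that("firing features follow their defining formulas", {
  # synthetic AP tables exercise the formulas directly
  rec <- simulate_current_steps(neuron_params("FS", noise_sd = 0),
                                step_protocol(), seed = 1)
  aps <- tibble::tibble(
    sweep = c(1, 1, 1, 2, 2),
    peak_time = c(100, 200, 300, 150, 250),
    amplitude = c(80, 78, 76, 90, 90),
    threshold_voltage = -50, ahp_depth = 10,
    half_width = 0.2, max_upstroke = 500, min_downstroke = -400,
    threshold_time = c(99, 199, 299, 149, 249))
  ff <- firing_features(rec, aps)
  # sweep 1: mean ISI 100 ms / 3 APs = 33.33 ms/spike (only qualifying sweep)
  expect_equal(ff$isi_accommodation_norm, 100 / 3, tolerance = 1e-6)
  # amplitudes 80, 78, 76 -> mean consecutive change -2; sweep 2 contributes 0
  expect_equal(ff$ap_amp_adaptation, mean(c(-2, 0)))
})

test_that("rheobase equals the brute-force sweep scan", {
  rec <- simulate_current_steps(neuron_params("FS"), step_protocol(),
                                seed = 2)
  aps <- detect_recording_aps(rec)
  ff <- firing_features(rec, aps)
  oracle <- min(rec$current_pa[rec$current_pa > 0 &
                                 vapply(rec$trace, function(tr)
                                   brute_force_spike_count(tr) > 0, TRUE)])
  expect_equal(ff$rheobase, oracle)
})

test_that("range scaling, constant columns and missing values behave as specified", {
  f <- tibble::tibble(cell_id = c("a", "b", "c"),
                      x = c(2, 4, 6), k = c(5, 5, 5), m = c(1, NA, 3))
  fm <- build_feature_matrix(f, registry = c("x", "k", "m"))
  expect_equal(fm$scaled$x, c(0, 0.5, 1))
  expect_equal(fm$scaled$k, c(0.5, 0.5, 0.5))
  expect_true(any(fm$flags$reason == "constant_column" &
                    fm$flags$feature == "k"))
  # NA imputed by the column median (2), then scaled
  expect_equal(fm$raw$m[2], NA_real_)
  expect_equal(fm$scaled$m[2], 0.5)
  expect_true(any(fm$flags$reason == "imputed_median" &
                    fm$flags$cell_id == "b"))
  expect_error(build_feature_matrix(
    tibble::tibble(cell_id = c("a", "b"), z = c(NA_real_, NA_real_)),
    registry = "z"), "z")
})

test_that("scaling is idempotent and invariant to cell order", {
  feats <- small_cohort_features()
  reg <- default_feature_registry()
  fm <- build_feature_matrix(feats, reg)
  fm2 <- build_feature_matrix(
    dplyr::rename(fm$scaled, cell_id = "cell_id"), reg)
  expect_equal(as.data.frame(fm2$scaled), as.data.frame(fm$scaled),
               tolerance = 1e-12)
  perm <- rev(seq_len(nrow(feats)))
  fmp <- build_feature_matrix(feats[perm, ], reg)
  expect_equal(as.data.frame(fmp$scaled[order(fmp$scaled$cell_id), ]),
               as.data.frame(fm$scaled[order(fm$scaled$cell_id), ]),
               ignore_attr = TRUE)
})

test_that("the default registry has 55 features and the matrix has 55 columns", {
  reg <- default_feature_registry()
  expect_length(reg, 55)
  feats <- small_cohort_features()
  fm <- build_feature_matrix(feats, reg)
  expect_equal(ncol(fm$scaled) - 1L, 55L)
})

test_that("every FS vs non-FS group difference reproduces in direction", {
  feats <- small_cohort_features()
  m <- function(f, cls) mean(feats[[f]][feats$cell_class == cls],
                             na.rm = TRUE)
  expect_lt(m("ap_halfwidth", "FS"), m("ap_halfwidth", "nonFS"))
  expect_lt(m("tau", "FS"), m("tau", "nonFS"))
  expect_lt(m("Rin", "FS"), m("Rin", "nonFS"))
  expect_lt(m("sag_ratio", "FS"), m("sag_ratio", "nonFS"))
  expect_lt(m("rheobase", "FS"), m("rheobase", "nonFS"))
  expect_gt(m("max_upstroke", "FS"), m("max_upstroke", "nonFS"))
  expect_lt(m("RMP", "FS"), m("RMP", "nonFS"))
  expect_gt(m("ap_amplitude", "FS"), m("ap_amplitude", "nonFS"))
})
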
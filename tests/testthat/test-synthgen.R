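test_that("a zero-current step holds the passive cell at its resting potential", {
  rec <- simulate_current_steps(passive_cell(),
                                step_protocol(n_steps = 1, start_current = 0),
                                seed = 1)
  expect_lt(max(abs(rec$trace[[1]] - (-65))), 0.01)
})

test_that("steady-state deflection follows Ohm's law on a passive cell", {
  rec <- simulate_current_steps(
    passive_cell(), step_protocol(n_steps = 1, start_current = -100),
    seed = 1)
  tr <- rec$trace[[1]]
  sr <- attr(rec, "sampling_khz")
  ss <- mean(tr[seq((900 - 100) * sr, 900 * sr)])  # last 100 ms of the step
  expect_equal(ss - (-65), -10, tolerance = 1e-3)
})

test_that("simulation is bit-reproducible given the seed", {
  p <- neuron_params("FS")
  a <- simulate_current_steps(p, step_protocol(n_steps = 5), seed = 99)
  b <- simulate_current_steps(p, step_protocol(n_steps = 5), seed = 99)
  expect_identical(a$trace, b$trace)
  pr1 <- simulate_paired_recording(seed = 7,
                                   protocol = pair_protocol(n_sweeps = 10))
  pr2 <- simulate_paired_recording(seed = 7,
                                   protocol = pair_protocol(n_sweeps = 10))
  expect_identical(pr1$sweeps$trace, pr2$sweeps$trace)
  expect_identical(pr1$ground_truth$quanta1, pr2$ground_truth$quanta1)
})

test_that("invalid neuron or protocol parameters raise errors", {
  expect_error(neuron_params("FS", membrane_capacitance = -1),
               "membrane_capacitance")
  expect_error(neuron_params("FS", leak_conductance = 0), "leak_conductance")
  expect_error(step_protocol(sampling_rate = 0), "sampling_rate")
  expect_error(synapse_params(release_prob_baseline = 1.2), "release_prob")
  expect_error(synapse_params(rise_tau = 3, decay_tau = 2), "rise_tau")
  expect_error(modulation_scenario("presynaptic_p_scale", scale_factor = 0),
               "scale_factor")
})

test_that("the protocol-grid rheobase matches a 1 pA brute-force scan", {
  for (cls in c("FS", "nonFS")) {
    p <- neuron_params(cls, noise_sd = 0)
    rec <- simulate_current_steps(p, step_protocol(), seed = 1)
    grid_rheo <- rec$current_pa[which(rec$n_true_spikes > 0 &
                                        rec$current_pa > 0)[1]]
    fine <- scan_rheobase(p, range_pa = c(20, 300), resolution = 1)
    # the smallest spiking 20 pA step is the grid point at or above the
    # continuously scanned rheobase
    expect_equal(grid_rheo, 20 * ceiling(fine / 20))
  }
})

test_that("deterministic release yields n_sites * quantal_amp on every first pulse", {
  syn <- synapse_params(release_prob_baseline = 1, facilitation_increment = 0,
                        depression_fraction = 0, noise_sd_current = 0)
  pr <- simulate_paired_recording(syn, protocol = pair_protocol(n_sweeps = 8),
                                  seed = 3)
  expect_true(all(pr$ground_truth$quanta1 == syn$n_sites))
  ev <- measure_connection(pr, noise_sd_estimate = 1)
  f1 <- ev[ev$pulse == 1, ]
  expect_false(any(f1$is_failure))
  expect_equal(f1$amplitude,
               rep(syn$n_sites * syn$quantal_amp, 8), tolerance = 0.02)
})

test_that("zero release probability produces only failures", {
  syn <- synapse_params(release_prob_baseline = 0)
  pr <- simulate_paired_recording(syn, protocol = pair_protocol(n_sweeps = 20),
                                  seed = 4)
  expect_true(all(pr$ground_truth$quanta1 == 0))
  ev <- measure_connection(pr, noise_sd_estimate = syn$noise_sd_current)
  expect_true(all(ev$is_failure))
})

test_that("mean first-pulse amplitude and failure rate match the binomial law", {
  syn <- synapse_params(n_sites = 8, release_prob_baseline = 0.33,
                        quantal_amp = 23.7)
  pr <- simulate_paired_recording(syn,
                                  protocol = pair_protocol(n_sweeps = 800),
                                  seed = 12)
  ev <- measure_connection(pr)
  f1 <- ev[ev$pulse == 1, ]
  # binomial mean n*p*q over all sweeps (failures as 0)
  amp_all <- ifelse(f1$is_failure, 0, f1$amplitude)
  mu <- syn$n_sites * syn$release_prob_baseline * syn$quantal_amp
  sd_k <- sqrt(syn$n_sites * 0.33 * 0.67) * syn$quantal_amp
  expect_lt(abs(mean(amp_all) - mu), 3 * sd_k / sqrt(800) + 0.01 * mu)
  # failure probability (1 - p)^n
  f_true <- (1 - syn$release_prob_baseline)^syn$n_sites
  se <- sqrt(f_true * (1 - f_true) / 800)
  expect_lt(abs(mean(f1$is_failure) - f_true), 3 * se)
})

test_that("mean sweep PPR matches the Monte-Carlo oracle of the release recursion", {
  syn <- synapse_params()
  pr <- simulate_paired_recording(syn,
                                  protocol = pair_protocol(n_sweeps = 500),
                                  seed = 21)
  k1 <- pr$ground_truth$quanta1; k2 <- pr$ground_truth$quanta2
  ok <- k1 > 0 & k2 > 0
  sim_ppr <- mean(k2[ok] / k1[ok])
  set.seed(77)
  oracle <- mc_expected_ppr(syn, ipi = pr$protocol$interpulse_interval)
  expect_lt(abs(sim_ppr - oracle["mean"]),
            3 * oracle["sd"] / sqrt(sum(ok)))
})

test_that("presynaptic scaling lowers PPR; postsynaptic scaling leaves released quanta untouched", {
  proto <- pair_protocol(n_sweeps = 1000)
  pre <- simulate_paired_recording(
    synapse_params(), modulation_scenario("presynaptic_p_scale", 1.3,
                                          onset_time = 5000),
    proto, seed = 31)
  gt <- pre$ground_truth
  ppr_of <- function(k1, k2, sel) {
    ok <- sel & k1 > 0 & k2 > 0
    mean(k2[ok] / k1[ok])
  }
  base <- pre$sweeps$epoch == "baseline"
  expect_lt(ppr_of(gt$quanta1, gt$quanta2, !base),
            ppr_of(gt$quanta1, gt$quanta2, base))

  none <- simulate_paired_recording(synapse_params(), modulation_scenario(),
                                    proto, seed = 31)
  post <- simulate_paired_recording(
    synapse_params(), modulation_scenario("postsynaptic_q_scale", 1.3,
                                          onset_time = 5000),
    proto, seed = 31)
  # identical seeds, identical release draws: q scaling cannot change them
  expect_identical(none$ground_truth$quanta1, post$ground_truth$quanta1)
  expect_identical(none$ground_truth$quanta2, post$ground_truth$quanta2)
})

test_that("washout restores pre-onset release statistics", {
  mod <- modulation_scenario("presynaptic_p_scale", 1.5, onset_time = 1000,
                             washout_time = 3000)
  pr <- simulate_paired_recording(synapse_params(), mod,
                                  pair_protocol(n_sweeps = 500), seed = 41)
  gt <- pr$ground_truth
  k1 <- gt$quanta1
  base <- mean(k1[pr$sweeps$epoch == "baseline"])
  ag <- mean(k1[pr$sweeps$epoch == "agonist"])
  wo <- mean(k1[pr$sweeps$epoch == "washout"])
  expect_gt(ag, base)
  se <- sd(k1) / sqrt(sum(pr$sweeps$epoch == "washout"))
  expect_lt(abs(wo - base), 4 * se)
})

test_that("leak-block modulation rescales conductance, Rin and holding current as Ohm's law dictates", {
  p <- neuron_params("FS", leak_conductance = 10, leak_reversal = -90)
  m <- modulation_scenario("leak_block", leak_scale = 0.8)
  p2 <- apply_modulation_effect(p, m)
  expect_equal(p2$leak_conductance, 8)
  expect_equal((1 / p2$leak_conductance) / (1 / p$leak_conductance), 1.25)
  # holding-current shift at -70 mV clamp: (V - E) * delta_g = 20 * (-2) nS*mV
  v_hold <- -70
  delta_i <- (v_hold - p$leak_reversal) *
    (p2$leak_conductance - p$leak_conductance)
  expect_equal(delta_i, -40)
  # identity at leak_scale = 1
  p3 <- apply_modulation_effect(p, modulation_scenario("leak_block",
                                                       leak_scale = 1))
  expect_identical(unclass(p3), unclass(p))
  expect_error(modulation_scenario("leak_block", leak_scale = 0),
               "leak_scale")
  expect_error(apply_modulation_effect(p, modulation_scenario()),
               "leak_block")
})
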
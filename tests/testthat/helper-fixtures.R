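# Small shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# 8 + 8 cell cohort with extracted features (moderate size, reused by the
# feature-matrix and classification tests)
small_cohort_features <- function() {
  if (is.null(.fixture_env$feats)) {
    coh <- simulate_step_cohort(8, c("FS", "nonFS"), seed = 11)
    .fixture_env$cohort <- coh
    .fixture_env$feats <- extract_cohort_features(coh)
  }
  .fixture_env$feats
}

small_cohort <- function() {
  invisible(small_cohort_features())
  .fixture_env$cohort
}

# the default 40-cell study cohort (20 per class, simulation seed 1),
# shared by the calibrated-recovery and classification-recovery checks
study_cohort_features <- function() {
  if (is.null(.fixture_env$feats40)) {
    coh <- simulate_step_cohort(20, c("FS", "nonFS"), seed = 1)
    .fixture_env$feats40 <- extract_cohort_features(coh)
  }
  .fixture_env$feats40
}

# a purely passive RC cell: 100 MOhm, 10 ms, no sag, no spikes, no noise
passive_cell <- function(noise_sd = 0) {
  neuron_params("FS",
                membrane_capacitance = 100, leak_conductance = 10,
                leak_reversal = -65, spike_threshold = 1000,
                adaptation_increment = 0, sag_conductance = 0,
                noise_sd = noise_sd)
}
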
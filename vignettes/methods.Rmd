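---
title: "Models and methods behind pairephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pairephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

pairephys implements the analysis chain of a paired-recording
neuromodulation study — interneuron classification from current steps,
per-connection EPSC/PPR/failure quantification with modulation
categorization, and intrinsic-property analysis — together with a synthetic
generator that produces recordings with the statistical structure the
analysis assumes. This vignette explains the underlying models, the
parameters that matter, the numerical conventions, and what the synthetic
data do and do not establish.

## The neuron model

Current-step recordings are simulated with an adaptive exponential
integrate-and-fire (AdEx) neuron extended by two elements:

* a **sag conductance** `g_sag` with sigmoidal steady-state activation below
  `sag_vhalf` (mV) and first-order kinetics (`sag_time_constant`, ms),
  reversing at −40 mV. It produces the depolarizing rebound during
  hyperpolarizing steps that the sag-ratio feature quantifies.
* a **stylized spike waveform**: when the membrane passes the numerical
  spike cutoff, a raised-sine (`sin²`) rise of height `spike_amplitude` and
  a raised-sine decay of depth `spike_amplitude + ahp_depth` are written
  into the trace, after which integration resumes from the
  after-hyperpolarization with the adaptation current incremented. The rise
  and decay durations are derived from `spike_upstroke_gain` and
  `spike_repolarization_gain` (mV/ms), which are exactly the maximal dV/dt
  of the two phases. This makes spike width, amplitude and dV/dt extrema
  directly controllable — every extracted feature has an analytic
  counterpart — without conductance-based channel models, which are out of
  scope on purpose: the *features* are under test, not the biophysics.

Membrane noise is additive Gaussian, scaled so its stationary standard
deviation equals `noise_sd` (mV). Integration is forward Euler at the
protocol sampling rate (default 50 kHz; a 0.18 ms spike then spans ~9
samples, enough for interpolation-based half-widths). All randomness flows
through R's RNG, so a seed makes every trace bit-reproducible.

The built-in `FS` and `nonFS` parameter sets were calibrated by fixed-point
iteration against the package's own feature extraction on noiseless traces
(`scripts/calibrate_defaults.R`): leak conductance, capacitance, leak
reversal, sag conductance, spike threshold and waveform gains were adjusted
until extracted Rin, τ, resting potential, sag ratio, rheobase, AP
half-width and amplitude match the fast-spiking and non-fast-spiking class
means the generator is meant to emulate (0.18 vs 0.43 ms half-width, 77 vs
112 MΩ, 4.0 vs 6.6 ms, 0.16 vs 0.34 sag, ~85 vs ~187 pA rheobase, −63 vs
−60 mV). The non-FS archetype uses slower, lower-threshold sag kinetics
(100 ms, −72 mV) than the FS archetype (40 ms, −75 mV), reflecting its much
larger sag. Cohorts add independent log-normal jitter to conductances,
capacitance and waveform gains and Gaussian jitter to voltages
(`draw_cohort_params()`); the dispersions are chosen for a *single*
archetype per class, so the within-class spread of spike kinetics is
narrower than in real non-FS populations, which mix several subtypes. That
is deliberate: class recovery and calibrated means are the quantities under
test, not subtype diversity.

## The synapse model

Connections are multi-site binomial release models. Each of the two
stimuli per sweep releases `Binomial(available sites, p)` quanta; released
sites depress (become unavailable with probability `depression_fraction`)
and recover with `recovery_time_constant`; the second pulse sees a
facilitated probability `p·(1 + facilitation_increment)`. The EPSC is a
difference of exponentials (`rise_tau` = 0.2 ms, `decay_tau` = 2 ms)
scaled by quanta, with per-event latency jitter and additive current
noise. Latency is defined as presynaptic AP peak → EPSC *onset*, with
onset operationalized as the detectable foot of the EPSC (20 % of peak) —
the same operational definition the measurement uses, since reported
latencies in this field are themselves onset-detected quantities.

The defaults (20 sites, p = 0.5, q = 6.3 pA, facilitation 0.31, depression
0.90, recovery 120 ms) were tuned by Monte-Carlo so that a baseline
connection shows a mean first-pulse EPSC near 62 pA and a *sweep-ratio*
mean PPR ≈ 1.03. Two consequences of this convention deserve note:

* Averaging per-sweep amplitude ratios carries an upward Jensen bias
  (E[a2/a1] > E[a2]/E[a1]) that grows as quantal content falls. A
  low-content synapse that matches a ~4 % failure rate cannot
  simultaneously have a sweep-ratio mean PPR of 1.03; the default
  therefore sits in a higher-content regime where failures are rare. The
  failure-rate machinery (threshold `max(5 pA, 3·noise SD)`, the binomial
  `(1−p)^n` law) is exercised by tests at explicitly low-content parameter
  settings instead.
* The higher-content regime also keeps the per-sweep PPR distribution
  tight enough that the pre/postsynaptic dissociation — presynaptic
  scaling shifts PPR down, postsynaptic scaling leaves the released-quanta
  ratio untouched — is resolvable per connection by a Mann–Whitney test on
  sweep PPRs at 300 sweeps per epoch, the property the package's
  dissociation analysis relies on.

Modulation scenarios multiply release probability
(`presynaptic_p_scale`), quantal amplitude (`postsynaptic_q_scale`) or the
postsynaptic leak conductance (`leak_block`; `mixed` combines the first
and last) between onset and washout. Under voltage clamp the leak model
implies `ΔI_hold = (V_hold − E_leak)·Δg` and `Rin ∝ 1/g`, which the
intrinsic analysis recovers exactly on noiseless traces. The leak driving
force uses a potassium-like reversal (−90 mV), so blocking leak shifts the
holding current inward — the depolarizing signature expected from
G\_q-coupled suppression of leak potassium channels. Holding-current
analyses baseline-subtract per cell, so the absolute holding level is
immaterial.

## Feature extraction conventions

* **AP detection**: upward crossing of dV/dt ≥ 20 mV/ms with a subsequent
  local maximum above −10 mV; double detections within 1 ms merge. The
  threshold point is the criterion crossing; "AP amplitude" is peak minus
  threshold voltage (the quantity is not otherwise standardized).
* **Half-width**: linear-interpolated crossings of threshold + amplitude/2
  on both flanks; flagged missing if the decay never recrosses before the
  next event.
* **Passive features**: RMP is the pre-stimulus mean; τ comes from a
  single-exponential fit over the first 100 ms of each hyperpolarizing
  step, excluding the first 2 ms (pipette transient), averaged across
  steps; fits pinned at the window bound are treated as failures rather
  than averaged in. Rin averages steady-state deflection / current over
  hyperpolarizing steps (steady state = last 100 ms). Sag ratio is
  `(V_min − V_ss)/(V_min − V_baseline)` on the −100 pA step, measured on a
  2 ms boxcar-smoothed trace so the minimum is not set by the noise floor.
* **Firing features**: rheobase is the first ascending step with ≥ 1 AP
  (so cohort means sit slightly above the continuous rheobase — the grid
  quantizes upward); normalized ISI accommodation is the per-sweep mean
  ISI divided by AP count, averaged over sweeps with ≥ 3 APs (ms/spike);
  amplitude adaptation is the mean of consecutive amplitude differences,
  later minus earlier, so adapting cells give negative values.
* **The 55-feature registry**: the 11 reported features plus supporting
  scalars and per-step features (spike counts per depolarizing step;
  deflection, fitted τ and sag per hyperpolarizing step). The identity of
  the full published feature set is not specified anywhere, so the
  composition is a package convention; entries were chosen to be
  *continuous* across cells. An earlier draft used per-step first-spike
  latencies censored at the step duration; those columns are near-binary
  across cells (800 ms vs ~20 ms, jumping at each cell's rheobase) and
  created artificial discrete substructure within classes. Range scaling
  maps each feature to [0, 1]; constant columns become 0.5 and are
  flagged; missing values are imputed with the column median and flagged;
  a column with no finite value is an error.

## Classification

UMAP (uwot) with 4 neighbors, min_dist 0.2, Euclidean metric on the scaled
matrix; k-means (k = 2, 25 restarts) on the 2-D coordinates; silhouette
validation on the same coordinates; the cluster with the smaller median
raw half-width is FS (ties broken by the larger median upstroke). k = 2 is
fixed a priori; `classify_cells(diagnostics = TRUE)` also reports
silhouettes for k = 2…5, for inspection only. A mean silhouette below 0.25
flags the partition "unvalidated" without changing labels — the threshold
is a package convention, since no standard acceptance value exists.

One numerical choice matters at small cohort sizes: with only 4 neighbors
the fuzzy graph of a 40-cell cohort is sparse, and uwot's default SGD
learning rate (1.0) can tear a weakly connected class into separate
islands whose placement is seed-dependent; the k = 2 partition then cuts
between islands instead of between classes. `embed_cells()` therefore runs
the layout with `learning_rate = 0.05`, which preserves the global
arrangement of the spectral initialization. The manifold hyperparameters
themselves (neighbors, min_dist, metric) are the published settings and
are not altered.

Both the embedding and the clustering take explicit seeds (default 42) and
are single-threaded, so `(matrix, seed)` fully determines the labels.

## Synaptic and intrinsic statistics

Per-connection categorization compares sweep-wise first-pulse amplitudes
(failures excluded) between the baseline window (−200…0 s relative to
wash-in) and the agonist window (60…260 s; the 60 s offset lets the bath
concentration equilibrate) with a two-sided Mann–Whitney test at α = 0.05,
uncorrected across connections — categorization is per connection by
design. The alternative convention of using the first minutes after
break-in as baseline is supported by passing explicit windows. PPR uses
sweep-ratio averaging (see above); sweeps with a failure on either pulse
are excluded from PPR with the exclusion count reported. The interpulse
interval defaults to 60 ms with 50 ms available as a protocol option,
since both appear in practice.

The Mann–Whitney implementation uses the exact distribution when both
groups have ≤ 8 observations and no ties, and the tie-corrected normal
approximation otherwise; fully tied (degenerate) data report p = 1. Cohort
tables test baseline vs agonist per group with a paired t-test when
Shapiro–Wilk on the paired differences gives p ≥ 0.05 and the Wilcoxon
signed-rank test otherwise; all-zero differences are flagged and reported
as p = 1. Category percentages round to the nearest integer percent.
Pearson correlations require ≥ 3 finite pairs and raise an error on
zero-variance input rather than returning NaN.

Per-cell intrinsic categories (holding current, Rin) come from two-sided
Mann–Whitney tests on 10 s bin means / per-sweep test-pulse estimates at
α = 0.05 — the per-cell test behind published pie-chart style summaries is
never stated, so this is a package convention. The −5 mV, 40 ms test pulse
inserted by the generator is standard voltage-clamp Rin monitoring.

## What the synthetic data do not show

The generator reproduces the statistical structure the analysis assumes:
calibrated class means, binomial release with short-term plasticity,
latency jitter, leak-block physics, access-resistance drift. It does not
emulate electrode artifacts, series-resistance error on EPSC amplitudes,
temperature or liquid-junction effects, subtype diversity within classes,
spontaneous synaptic events, or rundown. Passing tests therefore establish
that the pipeline recovers known ground truth under its own model
assumptions — a necessary condition, not evidence about any particular
real dataset.

## Problem sizes and runtime choices

The test suite uses an 8 + 8-cell cohort for feature/classification unit
tests, the 20 + 20-cell cohort (simulation seed 1) for calibrated
recovery and label recovery across 10 embedding seeds, 300-sweep
recordings for latency/PPR recovery, 50 seed-paired runs at 300 sweeps
per epoch for the mechanism-dissociation property, and exhaustive oracles
(Mann–Whitney enumeration up to 8 + 8, k-means partition enumeration up to
n = 8, local-maximum spike counting over > 1000 sweeps). These sizes keep
every Monte-Carlo tolerance at ≥ 3 standard errors while the full suite
runs in a few minutes on one core.

## Known limitations

* The stylized spike waveform reproduces half-width, amplitude and dV/dt
  extrema but not the curvature details of real spikes (e.g. biphasic
  repolarization); features beyond the calibrated set should not be
  over-interpreted.
* Sweep-ratio PPR averaging is biased upward at low quantal content (see
  above); comparisons across epochs are unaffected because the bias is
  common to both.
* The binomial/short-term-plasticity release model is an artifact stand-in
  for unrecorded presynaptic biophysics; its parameters are not estimates
  of any real synapse.
* With 4-neighbor UMAP at 40-cell scale the embedding remains sensitive to
  optimizer settings; the conservative learning rate stabilizes it, but
  larger cohorts (or more neighbors, where appropriate) are the robust
  remedy.
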
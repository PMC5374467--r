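---
title: "Decoding trajectory and muscle activity from ECoG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding trajectory and muscle activity from ECoG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecogdecode)
```

# The scientific problem

When a person carries an object along a fixed path, cortical activity over
the sensorimotor cortex carries two kinds of movement information:
*extrinsic* information about the object's trajectory in external space,
which is the same whatever the object weighs, and *intrinsic* information
about muscle activation, which scales with the load.  `ecogdecode`
implements a decoding pipeline that predicts both object kinematics and
muscle activation envelopes from multichannel electrocorticography (ECoG),
and then asks the weight matrices of those decoders where each kind of
information lives on the electrode grid.

The pipeline has five stages, each its own module:

1. **Feature extraction** — band-limited amplitude envelopes of each
   channel at 100 Hz (`ecog_features()`),
2. **Sparse decoding** — lag-embedded Bayesian linear regression with
   automatic relevance determination (`build_lagged_design()`,
   `fit_slir()`),
3. **Evaluation** — leave-one-trial-out cross-validation with RMSE and
   Pearson correlation (`decode_loocv()`), normalized-time resampling and
   one-way ANOVA contrasts (`resample_trial()`, `anova_timepoints()`),
4. **Weight analysis** — normalized electrode weight maps, frequency-band
   shares, premotor-vs-primary-motor t-tests, mass-transfer matrices and
   single-channel contribution maps (`weight_map()`, `band_weight_ratio()`,
   `region_ttest()`, `transfer_matrix()`, `contribution_map()`),
5. **Synthetic sessions** — a generator that emulates the object-carrying
   task with known ground truth (`generate_session()`), so the whole
   pipeline is testable end to end without patient data.

# Signal processing

## ECoG features

Raw ECoG (channels × samples at 1000 Hz) is processed as:

1. common average reference: the cross-channel mean is subtracted at every
   sample;
2. decomposition into nine bands with fourth-order Butterworth band-pass
   filters — δ 0.1–4, θ 4–8, α 8–14, β1 14–20, β2 20–30, γ1 30–60,
   γ2 60–90, γ3 90–120, γ4 120–150 Hz;
3. full-wave rectification (for the *rectified* feature variant; the
   *unrectified* variant skips this step, preserving the sign of slow
   potentials, which matters mostly in the δ band);
4. smoothing with a unit-area Gaussian window of time constant
   σ = 0.04 s, truncated at ±4σ;
5. down-sampling to 100 Hz by plain decimation (the Gaussian window is the
   anti-alias stage);
6. z-scoring per feature, `z_i(t) = (x_i(t) − μ_i)/σ_i`, with the sample
   standard deviation (denominator n−1).

With *n* electrodes and both variants this yields *n* × 9 × 2 features.
Design choices worth knowing about:

* **Zero-phase filtering.** All filters are applied forward–backward
  (`signal::filtfilt`), so features have no band-dependent group delay.
  This is the right choice for offline decoding analyses; a causal mode
  would be needed for closed-loop use and is available through
  `bandpass_filterbank(zero_phase = FALSE)`.
* **δ band lower edge.** The δ band is a 0.1–4 Hz *band-pass*, not a
  low-pass: the 0.1 Hz high-pass edge suppresses DC drift while keeping
  slow movement-related potentials.
* **Gaussian window.** The smoother is parameterized by its time constant
  (σ = 0.04 s).  A nominal cutoff of 3.98 Hz is recorded in the
  configuration as metadata; note that no standard cutoff convention makes
  a σ = 0.04 s Gaussian correspond exactly to 3.98 Hz, so the time
  constant is authoritative here and the cutoff is descriptive.
* **Edge handling.** The smoother replicates edge samples, so a constant
  signal maps to itself exactly (unit DC gain).

## EMG envelopes

Muscle activation is estimated from raw EMG by: 30–400 Hz band-pass
(second-order Butterworth, zero-phase) → full-wave rectification →
second-order low-pass at 2.2 Hz (zero-phase) → down-sampling to 100 Hz.
The recovered envelope correlates ≥ 0.95 with the generating envelope on
amplitude-modulated noise fixtures (see `test-preprocess.R` and the
acceptance script).

# The sparse decoder

The decoder predicts a target `Y_p(t)` (an object coordinate in mm, or a
muscle envelope in arbitrary units) as a linear readout of the lag-embedded
features:

    Y_p(t) = w0 + Σ_i Σ_j w_ij · z_i(t − j·Δt),   j = 0 … m−1

The reference configuration uses m = 100 lags spaced Δt = 0.01 s (a 1 s
history per feature).  Lags may reach across trial boundaries into the
continuous inter-trial rest, never off the recording start; rows without a
complete lag window are dropped and counted.

Weights are estimated by sparse Bayesian linear regression with automatic
relevance determination (ARD): each weight has an independent zero-mean
Gaussian prior with its own precision α_ij, and hyperparameters are updated
by evidence maximization — closed-form posterior mean and covariance, then
`α ← γ/μ²` with `γ = 1 − α·Σ_jj`, then the noise precision
`β ← (n − Σγ)/RSS` — iterated until both the weights and the precisions are
stable (relative change below 1e-6, at most 500 sweeps).  The bias `w0` is
unpenalized.  One independent model is fitted per output dimension.

Numerical design points:

* **Internal response standardization.** The fit is performed on
  `y/sd(y)` and rescaled afterwards.  This makes the relevance precisions
  dimensionless and the fit exactly equivariant under rescaling of the
  target, so the same pruning threshold applies to a target measured in
  millimetres and to one in arbitrary units.
* **Pruning threshold.** A weight is pruned to exactly zero when its
  (dimensionless) precision exceeds 1e3, i.e. when its posterior magnitude
  falls below about 3% of a response standard deviation.  This threshold
  was chosen from the structure of the ARD fixed points: features that
  merely fit residual noise stabilize at precisions of about 1e4 and
  above, while genuinely informative features sit orders of magnitude
  lower, so 1e3 separates the regimes with about an order of magnitude of
  margin on each side.  (A very large threshold such as 1e12 effectively
  disables pruning at realistic noise levels: the noise-fitting fixed
  points are *stable*, and are also why reference ARD implementations
  default to thresholds near 1e4.)  The threshold is configurable
  (`prune_alpha`), and pruning is permanent.
* **Convergence.** Stopping requires hyperparameter stability as well as
  weight stability; otherwise weights on their way to pruning (whose
  precisions grow geometrically) would be frozen by an early stop.
* **Deterministic fitter.** Initialization is fixed (α = 1 on the
  standardized scale, β = 1/var(y)), so the fit has no seed sensitivity.
* **Ridge cross-check.** With both hyperparameter updates disabled the fit
  equals closed-form ridge regression to 1e-6, which the test suite
  asserts against an independent direct solve.

# Evaluation

Cross-validation is **leave-one-trial-out**: folds are trials, because
samples within a trial are strongly dependent through the lag embedding and
sample-level leave-one-out would leak.  Per fold, normalization statistics
are recomputed from the training trials only and applied to the held-out
trial (`zscore_scope = "training"`, the default; a whole-session mode is
available for comparison with analyses that normalize per session).  A
NaN-poisoning test asserts that held-out samples never enter training.

Reported metrics: per-trial RMSE and Pearson CC; pooled RMSE/CC over the
concatenated held-out predictions; and the mean of per-trial values — the
pooled and trial-mean versions answer different questions and are reported
side by side.  A fold whose prediction (or target) is constant has
undefined CC; it is recorded as `NA`, excluded from means, and counted.
When *no* fold has a defined CC the mean absolute CC is reported as 0: a
constant predictor carries no linear association, which is the quantity the
null analyses measure.

Trials of different durations are compared on a normalized-time grid:
linear interpolation onto 200 equally spaced points of τ = t/T.
Between-mass contrasts use a standard one-way fixed-effects ANOVA at
selected τ (0.25, 0.5, 0.75 by default).

# Weight analysis

* **Weight maps** normalize by the global maximum, `|w_ij|/|w_max|`, and
  aggregate per channel by summing normalized magnitudes over bands,
  variants and lags (robust to the lag count; a max-over-lags option would
  be a one-line change but the sum is the default).  Maps are invariant to
  target rescaling.
* **Region contrast** is a two-sample Student (equal-variance) t-test on
  the per-feature normalized magnitudes of premotor vs primary-motor
  channels; Welch is available via `var_equal = FALSE`, and a per-channel
  aggregate population via `aggregate = "channel"`.  Per-feature is the
  default because it uses the full weight population rather than one
  number per electrode.
* **Band shares** are Σ|w| per band over Σ|w| total, also split by
  variant.
* **Mass transfer.** For each training mass, the family of leave-one-
  trial-out fold decoders is evaluated on its own held-out trials (the
  diagonal — exactly the within-mass LOO result) and, unchanged and with
  the same training-trial normalization statistics, on all trials of every
  other mass (off-diagonals).  Using the *same* decoders on both sides
  makes each row a pure data-transfer contrast, uncontaminated by
  training-set-size differences.  With several coordinate targets the
  residuals are pooled into a single trajectory RMSE.
* **Contributions.** For a chosen mass pair and path, the full-model
  prediction and each channel's single-channel prediction (that channel's
  weights only, bias excluded) are trial-averaged on the 200-point τ grid;
  each channel's contribution is the mean of its between-mass difference
  curve over τ ∈ [0.4, 0.6] (endpoints inclusive on the τ grid), as a
  percentage of the full-model mean difference.  Because the model is
  linear and the bias cancels in differences, the signed percentages sum
  to exactly 100; channels may legitimately carry negative percentages.
  When the full-model mean difference is below 1e-9 the percentages are
  undefined and the function refuses rather than report unstable numbers.

# The synthetic task world

`generate_session()` builds a complete session with known ground truth:

* **Task.** Objects of 25, 250 and 500 g are carried along a half-ellipse
  arc (semi-axes 200 and 150 mm) through (200, 0) → (0, 150) → (−200, 0)
  mm, alternately in the two directions, with minimum-jerk timing
  s(τ) = 10τ³ − 15τ⁴ + 6τ⁵ (zero endpoint velocity and acceleration) and a
  single-bump vertical lift (default 50 mm, configurable — carrying height
  is a free parameter of the task).  Default trials last 2 s ± 5% with 1 s
  of rest; the rest guarantees that a 1 s lag window never reaches into a
  neighbouring trial, and the lead-in keeps it on the recording.  Twelve
  trials per mass (6 per direction) keep the default study tractable;
  masses are run in blocks, like separate recording sessions.
* **Muscles.** Each muscle's activation is a smooth bump over the trial
  with peak amplitude `path_gain · (a0 + a1·mass)`.  The elbow flexor
  (biceps) carries the strong mass dependence (a1 = 0.005 a.u./g over
  a0 = 0.2) and peaks late (τ = 0.6), favouring one carrying direction;
  the extensor peaks early and favours the other; the posterior deltoid
  is mass-independent and direction-symmetric.  The phase- and
  direction-asymmetry is deliberate: real arm muscles recruit in phases
  and differ between leftward and rightward transport, and it makes
  intrinsic features genuinely informative about movement, not only about
  load.
* **ECoG.** Each channel is a sum of band-limited unit-variance noise
  carriers, amplitude-modulated as `1 + gain · driver01(t)` where the
  driver is object X, Y, speed, or a muscle envelope normalized to [0,1];
  extrinsic channels additionally carry a low-frequency additive component
  proportional to signed position (so unrectified δ features can decode
  signed coordinates); everything rides on 1/f plus white noise
  (σ = 1 and 0.5).  The default 4 × 5 grid plants six extrinsic channels
  in the premotor half, six intrinsic channels in the primary-motor half,
  two mixed channels in each (trajectory coding in one γ band, muscle
  coding in another), and leaves six channels as pure noise.
* **EMG and motion.** Raw EMG is the activation envelope times a
  30–400 Hz noise carrier (plus a 1% noise floor), so the published EMG
  pipeline recovers the envelope.  Motion is the trajectory sampled at
  30 Hz with 2 mm Gaussian jitter standing in for camera noise, and is
  cubic-interpolated to 100 Hz before fitting.
* **Determinism.** A session is a pure function of its configuration and
  seed.

What the generator does *not* emulate: biophysical cortical dynamics,
behavioural variability beyond duration jitter and motion noise, artifacts
and line noise, electrode impedance drift, or learning across trials.
Passing tests on this world show that the pipeline recovers structure that
is present; they cannot show how much structure real recordings contain.

# The default synthetic study

The packaged analyses (test suite and `scripts/acceptance.R`) run a scaled
study chosen to complete comfortably on one CPU: decoders use m = 5 lags at
Δt = 0.01 s with design rows every 50 ms (the synthetic couplings are
instantaneous, so a long lag history adds columns, not information), both
feature variants for the weight-map analyses, and 12 trials per mass.
Findings it reproduces, all computed at run time:

* trajectory-decoder weight mass concentrates on the planted
  extrinsic/mixed channels, and muscle-decoder weight mass on
  intrinsic/mixed channels (≥ 70% in both cases, typically > 90%);
* the muscle decoder's primary-motor (M1) weights exceed its premotor
  (PM) weights (Student t-test, p < 0.01) — the planted analog of an
  intrinsic-information concentration under M1;
* γ bands dominate the muscle decoder's band shares, while the
  trajectory decoders draw heavily on unrectified δ;
* leave-one-trial-out decoding reaches CC ≈ 0.99 for the X coordinate and
  ≈ 0.98 for the biceps envelope at the default noise levels;
* single-mass decoders degrade away from their training mass in the
  combined X/Y/Z transfer matrix (run in the rectified band-power feature
  space, where the effort coupling binds);
* per-channel contribution percentages sum to exactly 100, and the top
  contributors to the biceps mass difference are the planted biceps-coded
  channels;
* permuted targets decode at chance (mean |CC| < 0.1), and
  the ARD fitter recovers a planted 3-of-50 support exactly with
  coefficients matching an OLS-on-true-support oracle.

## Known limitations

* **Transfer margins for the X coordinate.** In this task world the X
  coordinate is monotone within a trial and nearly orthogonal to the
  effort bump, so its decoder is close to mass-invariant and its
  within-vs-cross-mass margins are small relative to estimation noise at
  12 trials per mass.  The combined-matrix row-wise degradation holds at
  the default configuration, but the minimum row margin can dip slightly
  below zero for some generator seeds; the acceptance script reports the
  minimum margin as a computed quantity so this is visible rather than
  hidden.  At larger trial counts the margins separate cleanly.
* **Unrectified features and transfer.** The clean additive δ components
  the generator plants make decoders that use them essentially
  mass-invariant — with the full feature set, single-mass decoders
  transfer almost perfectly in this synthetic world.  The transfer study
  therefore probes the rectified band-power space.  Real cortex offers no
  such perfectly clean slow potential, which is exactly why mass-specific
  decoders fail to transfer in practice.
* **ANOVA assumptions.** The time-point contrasts are fixed-effects
  one-way ANOVAs treating trials as independent; slow within-session
  drifts would violate this on real data.
* **The `cli_io` surface is programmatic.** Sessions are directories of
  CSV/TSV/JSON read and written by `read_session()`/`write_session()`,
  and `run_pipeline()` orchestrates the full analysis with a manifest and
  a configuration hash; there is no shell executable, since the package's
  users drive it from R.
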
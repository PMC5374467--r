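# ecogdecode

Sparse linear decoding of object trajectory and muscle activity from
electrocorticography (ECoG), with electrode weight-map analyses that ask
*where* trajectory (extrinsic) and muscle (intrinsic) information lives on
the grid.

## The problem and who this is for

In an object-carrying task, sensorimotor cortex carries both extrinsic
movement information (the object's path in space, independent of load) and
intrinsic information (muscle activation, scaling with load).  This package
is for neural-engineering and motor-control researchers who want to:

- extract band-resolved amplitude features from multichannel ECoG
  (nine Butterworth bands, δ 0.1–4 Hz through γ4 120–150 Hz, rectified and
  unrectified variants, Gaussian-smoothed, 100 Hz, z-scored);
- decode kinematics and EMG envelopes with a lag-embedded sparse Bayesian
  linear model (automatic relevance determination, ARD):

  `Y_p(t) = w0 + Σ_i Σ_j w_ij · z_i(t − jΔt)`, with m = 100 lags at
  Δt = 0.01 s by default;

- evaluate with leave-one-trial-out cross-validation (RMSE, Pearson CC),
  normalized-time trial averaging and one-way ANOVA contrasts;
- analyse the fitted weights: normalized maps `|w_ij|/|w_max|`, per-band
  weight shares, premotor-vs-primary-motor t-tests, mass-transfer matrices
  of single-mass decoders, and single-channel percentage contributions to
  between-mass differences.

Because clinical ECoG recordings are rarely shareable, the package ships a
first-class synthetic session generator (`generate_session()`) that
emulates the carrying task — arc trajectories through
(200, 0) → (0, 150) → (−200, 0) mm, three object masses (25/250/500 g),
mass-scaled muscle envelopes, and cortical channels whose band-limited
envelopes encode either kinematics or muscle activation — with known ground
truth, so every claim the pipeline makes can be checked against the plant.

## Worked example

```r
library(ecogdecode)

ses <- generate_session(task_config())   # deterministic synthetic session
ses
#> ecog_session: 20 channels x 110109 samples at 1000 Hz, 36 trials (25/250/500 g), 4 muscles

ft <- ecog_features(ses$ecog, ses$meta$fs_ecog_hz)
ft
#> feature_tensor: 360 features (20 channels x 9 bands x 2 variants), 11011 samples at 100 Hz

tg <- session_targets(ses)               # X/Y/Z (mm) and 4 EMG envelopes at 100 Hz

# scaled study settings (see the methods vignette): 5 lags at 10 ms
study <- decoder_config(m = 5, dt_s = 0.01, row_stride = 5)

# leave-one-trial-out decoding of the object's X coordinate
decode_loocv(ft, tg$x, ses$events, study)
#> cv_result: 36 folds, pooled RMSE 17.55, pooled CC 0.995, mean |CC| 0.997 (0 folds with undefined CC)

# where does the biceps decoder look?
fit <- fit_decoder(ft, tg$biceps, ses$events, study)
wm  <- weight_map(fit$model, fit$ftz$key, ses$meta)
head(sort(round(wm$per_channel, 2), decreasing = TRUE))
#>   11   17    8   16   12   18
#> 5.32 4.08 2.67 2.49 2.19 1.16

region_ttest(wm, ses$meta$region)
#> t(1798) = -3.719, p = 0.0002061 (PM mean 0.004038 vs M1 mean 0.01694)

contribution_map(fit, mass_pair = c(25, 500), path = 1)
#> contribution_map (25 vs 500 g, path 1, tau 0.40-0.60): top channels ch11 23.8%, ch17 22.1%, ch16 16.7%
```

Reading the output: the X decoder reaches CC ≈ 0.99 held-out; the biceps
decoder's weight mass sits on channels 11/12/16/17/18 — exactly the
channels the generator couples to muscle envelopes, all in the M1 half of
the grid (hence the t-test's M1 > PM means, p ≈ 2×10⁻⁴) — and the channels
contributing most to the predicted 25-vs-500 g difference are the planted
biceps-coded ones, with signed percentages that sum to exactly 100.

`run_pipeline(session, pipeline_config(), out_dir)` orchestrates the whole
analysis (features → decoders → LOO-CV → weight maps → transfer →
contributions) and writes TSV/JSON outputs plus a manifest keyed by a
configuration hash; `write_session()`/`read_session()` serialize sessions
as portable CSV/TSV/JSON directories.

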
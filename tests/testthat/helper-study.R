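# shared fixtures, built once per test run and cached

.study_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .study_cache))
    assign(key, force(expr), envir = .study_cache)
  get(key, envir = .study_cache)
}

# the canonical synthetic session (default task configuration)
default_session <- function() memo("session", generate_session(task_config()))

default_features <- function() memo("features", {
  ses <- default_session()
  ecog_features(ses$ecog, ses$meta$fs_ecog_hz)
})

default_targets <- function() memo("targets", session_targets(default_session()))

# decoder settings for the scaled synthetic study (documented in the
# methods vignette): 5 lags at 10 ms, design rows every 50 ms
study_config <- function() decoder_config(m = 5L, dt_s = 0.01, row_stride = 5L)

# rectified-only variant used for the mass-transfer study, denser rows
transfer_config <- function() decoder_config(m = 5L, dt_s = 0.01,
                                             row_stride = 2L,
                                             variants = "rectified")

study_fit <- function(target_name) {
  memo(paste0("fit_", target_name), {
    fit_decoder(default_features(), default_targets()[[target_name]],
                default_session()$events, study_config())
  })
}

# amplitude-modulated EMG fixture: band-limited noise carrier times a known
# slow envelope
make_am_fixture <- function(seed = 5, fs = 1000, dur_s = 10) {
  set.seed(seed)
  n <- dur_s * fs
  t <- (0:(n - 1)) / fs
  envelope <- 1 + 0.8 * sin(2 * pi * 0.4 * t) + 0.4 * sin(2 * pi * 0.9 * t + 1)
  carrier <- signal::filtfilt(signal::butter(2, c(30, 400) / (fs / 2), "pass"),
                              rnorm(n))
  list(raw = envelope * carrier / sd(carrier), envelope = envelope,
       fs = fs, t = t)
}

# small quiet session for structural tests
small_session <- function() memo("small_session", {
  cfg <- task_config(masses_g = c(25, 500), n_trials_per_mass = 2L,
                     trial_duration_s = 1.5, seed = 11L)
  generate_session(cfg)
})
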
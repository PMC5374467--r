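test_that("trajectory passes through the via points with min-jerk timing", {
  for (dur in c(1.5, 2.7)) {
    tr <- generate_trajectory(1, dur, lift_height_mm = 50, fs_hz = 1000)
    expect_equal(unlist(tr[1, c("X", "Y", "Z")]), c(X = 200, Y = 0, Z = 0),
                 tolerance = 1e-12)
    expect_equal(unlist(tr[nrow(tr), c("X", "Y", "Z")]),
                 c(X = -200, Y = 0, Z = 0), tolerance = 1e-9)
    mid <- tr[(nrow(tr) + 1) %/% 2, ]          # tau = 0.5
    expect_equal(unlist(mid[c("X", "Y", "Z")]), c(X = 0, Y = 150, Z = 50),
                 tolerance = 1e-9)
  }
  # path 2 is the reverse
  tr2 <- generate_trajectory(2, 2, fs_hz = 100)
  expect_equal(tr2$X[1], -200, tolerance = 1e-12)
  expect_equal(tr2$X[nrow(tr2)], 200, tolerance = 1e-9)
})

test_that("zero lift height gives a flat Z profile", {
  tr <- generate_trajectory(1, 2, lift_height_mm = 0, fs_hz = 200)
  expect_true(all(tr$Z == 0))
})

test_that("endpoint speeds are below 1% of peak speed", {
  tr <- generate_trajectory(1, 2, fs_hz = 1000)
  v <- sqrt(rowSums(diff(as.matrix(tr[, c("X", "Y", "Z")]))^2)) * 1000
  expect_lt(v[1], 0.01 * max(v))
  expect_lt(v[length(v)], 0.01 * max(v))
})

test_that("trajectory rejects invalid arguments", {
  expect_error(generate_trajectory(1, -1), "positive")
  expect_error(generate_trajectory(3, 1), "path")
})

test_that("muscle envelope amplitude is linear in mass with exact slope", {
  truth <- default_ground_truth()
  mk <- function(mass, path = 1L)
    list(t_start_s = 0, t_end_s = 2, path = path, mass_g = mass)
  e25 <- generate_muscle_activity(mk(25), truth)
  e500 <- generate_muscle_activity(mk(500), truth)
  a1 <- truth$muscle_mass_coeffs["biceps", "a1"]
  g1 <- truth$muscle_profile["biceps", "path1_gain"]
  expect_equal(max(e500["biceps", ]) - max(e25["biceps", ]),
               g1 * a1 * 475, tolerance = 1e-9)
  # the mass-independent muscle is identical across masses
  expect_equal(e25["deltoid_post", ], e500["deltoid_post", ])
  # non-negativity for every muscle and mass
  for (m in c(25, 250, 500))
    expect_true(all(generate_muscle_activity(mk(m), truth) >= 0))
})

test_that("all-zero mass slopes make envelopes mass-independent", {
  truth <- default_ground_truth()
  truth$muscle_mass_coeffs[, "a1"] <- 0
  mk <- function(mass) list(t_start_s = 0, t_end_s = 2, path = 1L,
                            mass_g = mass)
  expect_equal(generate_muscle_activity(mk(25), truth),
               generate_muscle_activity(mk(500), truth))
})

test_that("sessions are deterministic and keep trial books in order", {
  cfg <- task_config(masses_g = c(25, 500), n_trials_per_mass = 2L,
                     trial_duration_s = 1.2, seed = 77L)
  s1 <- generate_session(cfg)
  s2 <- generate_session(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$events), 2 * 2 * 2)
  # trials are disjoint and inside the recording
  ev <- s1$events
  expect_true(all(ev$t_end_s > ev$t_start_s))
  expect_true(all(head(ev$t_end_s, -1) <= tail(ev$t_start_s, -1)))
  expect_lt(max(ev$t_end_s), ncol(s1$ecog) / cfg$fs_ecog_hz)
})

test_that("grid metadata matches the configured layout", {
  ses <- small_session()
  cfg <- ses$config
  expect_equal(nrow(ses$ecog), cfg$grid_rows * cfg$grid_cols)
  expect_equal(diff(range(ses$meta$x_mm)), (cfg$grid_cols - 1) * cfg$pitch_mm)
  expect_equal(diff(range(ses$meta$y_mm)), (cfg$grid_rows - 1) * cfg$pitch_mm)
  expect_true(all(ses$meta$region %in% c("PM", "M1", "other")))
})

test_that("a single-band coupling concentrates spectral power in that band", {
  cfg <- task_config(masses_g = 25, n_trials_per_mass = 2L, grid_rows = 1L,
                     grid_cols = 2L, trial_duration_s = 1.5, seed = 3L)
  truth <- ground_truth(
    channel_class = c("extrinsic", "noise"),
    region = c("PM", "M1"),
    couplings = data.frame(channel = 1L, band = "gamma2", driver = "speed",
                           gain = 5),
    lowfreq = data.frame(channel = integer(0), driver = character(0),
                         gain = numeric(0)),
    muscle_mass_coeffs = matrix(c(rep(0.5, 4), rep(0, 4)), 4, 2,
                                dimnames = list(emg_muscles(), c("a0", "a1"))),
    pink_sd = 0, white_sd = 0)
  ses <- generate_session(cfg, truth)
  x <- ses$ecog[1, ]
  pg <- Mod(stats::fft(x - mean(x)))^2
  freq <- (seq_along(pg) - 1) / length(pg) * cfg$fs_ecog_hz
  half <- freq <= cfg$fs_ecog_hz / 2
  in_band <- half & freq >= 60 & freq <= 90
  slow <- half & freq < 1               # slow component excluded
  frac <- sum(pg[in_band]) / sum(pg[half & !slow])
  expect_gte(frac, 0.8)
})

test_that("a strongly coupled extrinsic channel's envelope tracks its driver", {
  ses <- default_session()
  ft <- default_features()
  tg <- default_targets()
  # channel 3 couples gamma2 to object speed at gain 5
  i <- which(ft$key$channel == 3 & ft$key$band == "gamma2" &
               ft$key$variant == "rectified")
  speed <- c(0, sqrt(diff(tg$x)^2 + diff(tg$y)^2 + diff(tg$z)^2)) * 100
  expect_gte(cor(ft$values[i, ], speed), 0.8)
})

test_that("simulated EMG shows the planted mass contrast after preprocessing", {
  ses <- default_session()
  env <- emg_envelope(ses$emg, ses$meta$fs_emg_hz)
  n_s <- ncol(env$values)
  res <- function(muscle) {
    mi <- match(muscle, emg_muscles())
    t(sapply(seq_len(nrow(ses$events)), function(k) {
      idx <- ecogdecode:::trial_sample_idx(ses$events, k, env$fs, n_s)
      resample_trial(env$values[mi, idx], 200L)
    }))
  }
  a_bic <- anova_timepoints(res("biceps"), ses$events$mass_g, taus = 0.5)
  a_pd <- anova_timepoints(res("deltoid_post"), ses$events$mass_g, taus = 0.5)
  expect_lt(a_bic$p, 0.01)        # mass-dependent muscle separates
  expect_gt(a_pd$p, 0.05)         # mass-independent muscle does not
})

test_that("invalid configurations are rejected", {
  expect_error(task_config(masses_g = c(25, 25)), "distinct")
  expect_error(task_config(n_trials_per_mass = 1), ">= 2")
  expect_error(task_config(trial_duration_s = 0), "positive")
  cfg <- task_config(grid_rows = 2L, grid_cols = 2L)
  expect_error(generate_session(cfg, default_ground_truth()), "channels")
  expect_error(ground_truth("noise", "PM",
                            data.frame(channel = 1L, band = "gamma1",
                                       driver = "speed", gain = 2),
                            data.frame(channel = integer(0),
                                       driver = character(0),
                                       gain = numeric(0)),
                            matrix(0, 4, 2,
                                   dimnames = list(emg_muscles(),
                                                   c("a0", "a1")))),
               "noise channels")
})
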
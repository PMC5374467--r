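#' Task configuration for the synthetic object-carrying session
#'
#' Describes the behavioural protocol that the synthetic generator emulates:
#' an object of known mass is carried along a half-ellipse arc on a table,
#' alternately in the two directions (path 1: (200, 0) -> (0, 150) ->
#' (-200, 0) mm; path 2 the reverse), with a rest between trials.
#'
#' @param masses_g Object masses in grams (default 25, 250, 500).
#' @param n_trials_per_mass Repetitions of the path-1/path-2 pair per mass;
#'   each pair yields two trials, so the session holds
#'   `2 * n_trials_per_mass * length(masses_g)` trials.
#' @param trial_duration_s Nominal trial duration in seconds (a +/- 5%
#'   uniform jitter is applied per trial).
#' @param inter_trial_s Rest between consecutive trials in seconds.
#' @param grid_rows,grid_cols Electrode grid shape.
#' @param pitch_mm Inter-electrode distance in mm.
#' @param fs_ecog_hz,fs_emg_hz,fs_motion_hz Sampling rates in Hz.
#' @param lift_height_mm Peak vertical excursion of the carried object.
#' @param seed RNG seed; identical configurations produce bit-identical
#'   sessions.
#' @return List of class `task_config`.
#' @export
task_config <- function(masses_g = c(25, 250, 500), n_trials_per_mass = 6L,
                        trial_duration_s = 2, inter_trial_s = 1,
                        grid_rows = 4L, grid_cols = 5L, pitch_mm = 10,
                        fs_ecog_hz = 1000, fs_emg_hz = 1000, fs_motion_hz = 30,
                        lift_height_mm = 50, seed = 1L) {
  for (nm in c("trial_duration_s", "inter_trial_s", "pitch_mm",
               "fs_ecog_hz", "fs_emg_hz", "fs_motion_hz"))
    check_scalar_pos(get(nm), nm)
  if (anyDuplicated(masses_g) || any(masses_g < 0))
    stop_invalid("masses must be distinct and non-negative")
  if (n_trials_per_mass < 2L)
    stop_invalid("n_trials_per_mass must be >= 2")
  structure(list(masses_g = masses_g,
                 n_trials_per_mass = as.integer(n_trials_per_mass),
                 trial_duration_s = trial_duration_s,
                 inter_trial_s = inter_trial_s,
                 grid_rows = as.integer(grid_rows),
                 grid_cols = as.integer(grid_cols),
                 pitch_mm = pitch_mm, fs_ecog_hz = fs_ecog_hz,
                 fs_emg_hz = fs_emg_hz, fs_motion_hz = fs_motion_hz,
                 lift_height_mm = lift_height_mm, seed = as.integer(seed)),
            class = "task_config")
}

#' Muscle names used throughout the package
#' @return Character vector of the four recorded upper-arm muscles.
#' @export
emg_muscles <- function() c("biceps", "triceps", "deltoid_ant", "deltoid_post")

#' Ground-truth channel structure for a synthetic session
#'
#' Defines which channels encode movement in extrinsic (trajectory)
#' coordinates, which in intrinsic (muscle) coordinates, and how strongly.
#' Each coupling row multiplies a band-limited unit-variance carrier by
#' `1 + gain * driver01(t)` where `driver01` is the named driver normalized
#' to [0, 1]; low-frequency rows add `gain * signed_position` directly to
#' the channel (supporting unrectified delta features).  Muscle envelope
#' amplitude is `a0 + a1 * mass_g` per muscle.
#'
#' @param channel_class Character vector, one of `"extrinsic"`,
#'   `"intrinsic"`, `"mixed"`, `"noise"` per channel.
#' @param region Character vector of region labels (`"PM"`, `"M1"`,
#'   `"other"`) per channel.
#' @param couplings Data frame with columns `channel`, `band`, `driver`
#'   (one of `pos_x`, `pos_y`, `speed`, or a muscle name) and `gain`.
#' @param lowfreq Data frame with columns `channel`, `driver` (`pos_x` or
#'   `pos_y`) and `gain`: additive slow components proportional to signed,
#'   unit-normalized position.
#' @param muscle_mass_coeffs Numeric matrix, muscles x `c(a0, a1)`.
#' @param muscle_profile Data frame with one row per muscle: `tau_peak`
#'   (normalized time of peak activation) and `path1_gain` / `path2_gain`
#'   (direction-dependent amplitude factors); `NULL` gives symmetric
#'   mid-trial bumps with unit gains.
#' @param pink_sd,white_sd Standard deviations of the 1/f and white noise
#'   components added to every channel.
#' @return List of class `ground_truth`.
#' @export
ground_truth <- function(channel_class, region, couplings, lowfreq,
                         muscle_mass_coeffs, muscle_profile = NULL,
                         pink_sd = 1, white_sd = 0.5) {
  stopifnot(length(channel_class) == length(region))
  if (!all(channel_class %in% c("extrinsic", "intrinsic", "mixed", "noise")))
    stop_invalid("unknown channel class")
  if (!all(region %in% c("PM", "M1", "other")))
    stop_invalid("unknown region label")
  if (nrow(couplings) && !all(is.finite(couplings$gain)))
    stop_invalid("coupling gains must be finite")
  noisy <- which(channel_class == "noise")
  if (any(couplings$channel %in% noisy) ||
      (nrow(lowfreq) && any(lowfreq$channel %in% noisy)))
    stop_invalid("noise channels must have all gains zero")
  if (is.null(muscle_profile))
    muscle_profile <- data.frame(tau_peak = rep(0.5,
                                                nrow(muscle_mass_coeffs)),
                                 path1_gain = 1, path2_gain = 1,
                                 row.names = rownames(muscle_mass_coeffs))
  structure(list(channel_class = channel_class, region = region,
                 couplings = couplings, lowfreq = lowfreq,
                 muscle_mass_coeffs = muscle_mass_coeffs,
                 muscle_profile = muscle_profile,
                 pink_sd = pink_sd, white_sd = white_sd),
            class = "ground_truth")
}

#' Default ground truth for a 4 x 5 grid
#'
#' Plants six extrinsic channels (gamma-band envelopes and additive
#' low-frequency components tracking object position and speed) in the
#' premotor half of the grid, six intrinsic channels (gamma envelopes
#' tracking muscle activation) in the primary-motor half, two mixed
#' channels in each (trajectory coding in one gamma band, muscle coding in
#' another), and leaves the rest as pure 1/f + white noise.  The biceps
#' carries the strong mass dependence (its envelope amplitude grows
#' linearly with object mass); the posterior deltoid is mass-independent.
#'
#' @param cfg A [task_config()]; the grid must hold at least 20 channels.
#' @return A [ground_truth()] object.
#' @export
default_ground_truth <- function(cfg = task_config()) {
  n_ch <- cfg$grid_rows * cfg$grid_cols
  if (n_ch < 20L)
    stop_invalid("default ground truth needs a grid of >= 20 channels")
  cls <- rep("noise", n_ch)
  cls[1:6] <- "extrinsic"
  cls[c(7L, 8L, 17L, 18L)] <- "mixed"
  cls[11:16] <- "intrinsic"
  region <- rep("other", n_ch)
  region[1:10] <- "PM"
  region[11:20] <- "M1"
  mixed_rows <- function(ch, pos_driver, traj_band, musc_band) {
    # a mixed channel carries trajectory coding in one gamma band and
    # muscle coding in another (extrinsic- and intrinsic-like populations
    # under the same electrode)
    data.frame(channel = ch, band = c(traj_band, musc_band),
               driver = c(pos_driver, "biceps"),
               gain = c(3, 5), stringsAsFactors = FALSE)
  }
  couplings <- rbind(
    data.frame(
      channel = 1:6,
      band = c("gamma2", "gamma2", "gamma2", "gamma1", "gamma1", "gamma2"),
      driver = c("pos_x", "pos_y", "speed", "pos_x", "pos_y", "speed"),
      gain = 5, stringsAsFactors = FALSE),
    mixed_rows(7L, "pos_x", "gamma2", "gamma1"),
    mixed_rows(8L, "pos_x", "gamma3", "gamma2"),
    mixed_rows(17L, "pos_y", "gamma1", "gamma3"),
    mixed_rows(18L, "pos_y", "gamma2", "gamma1"),
    data.frame(
      channel = c(11L, 11L, 12L, 13L, 14L, 15L, 16L),
      band = c("gamma1", "gamma3", "gamma2", "gamma1", "gamma2", "gamma1",
               "gamma3"),
      driver = c("biceps", "biceps", "biceps", "triceps", "deltoid_ant",
                 "deltoid_post", "biceps"),
      gain = 5, stringsAsFactors = FALSE))
  lowfreq <- data.frame(channel = c(1L, 3L, 5L, 2L, 4L, 6L),
                        driver = c("pos_x", "pos_x", "pos_x",
                                   "pos_y", "pos_y", "pos_y"),
                        gain = rep(5, 6), stringsAsFactors = FALSE)
  mmc <- matrix(c(0.2, 0.005,
                  0.8, 0.001,
                  1.0, 0.0005,
                  1.0, 0.0), 4L, 2L, byrow = TRUE,
                dimnames = list(emg_muscles(), c("a0", "a1")))
  # phase-ordered, direction-dependent recruitment: the elbow flexor peaks
  # late and favours the rightward carry, the extensor early and leftward,
  # the anterior deltoid slightly early; the posterior deltoid is uniform
  prof <- data.frame(tau_peak = c(0.6, 0.35, 0.45, 0.5),
                     path1_gain = c(0.8, 1.2, 1.1, 1.0),
                     path2_gain = c(1.2, 0.8, 0.9, 1.0),
                     row.names = emg_muscles())
  ground_truth(cls, region, couplings, lowfreq, mmc, muscle_profile = prof)
}

#' Arc trajectory for one carrying trial
#'
#' Traces a half-ellipse with semi-axes 200 mm (X) and 150 mm (Y) through
#' the via points (200, 0) -> (0, 150) -> (-200, 0) mm, with a single-bump
#' vertical lift, following a minimum-jerk timing law
#' `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5` so that velocity and
#' acceleration vanish at the endpoints.  Path 2 is the reverse direction.
#'
#' @param path 1 (start at x = +200 mm) or 2 (start at x = -200 mm).
#' @param duration_s Trial duration in seconds.
#' @param lift_height_mm Peak Z excursion in mm.
#' @param fs_hz Sampling rate of the returned series.
#' @return Data frame with columns `t`, `X`, `Y`, `Z` (mm); the first row
#'   is at t = 0 and the last at `t = duration_s`.
#' @export
generate_trajectory <- function(path, duration_s, lift_height_mm = 50,
                                fs_hz = 30) {
  check_scalar_pos(duration_s, "duration_s")
  check_scalar_pos(fs_hz, "fs_hz")
  if (!path %in% c(1, 2)) stop_invalid("path must be 1 or 2")
  n <- round(duration_s * fs_hz) + 1L
  tau <- seq(0, 1, length.out = n)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  if (path == 2) s <- 1 - s
  data.frame(t = tau * duration_s,
             X = 200 * cos(pi * s),
             Y = 150 * sin(pi * s),
             Z = lift_height_mm * sin(pi * s))
}

# smooth non-negative activation bump over normalized trial time,
# peak-normalized to 1 at tau_peak (beta-shaped; k controls width)
activation_bump <- function(tau, tau_peak = 0.5, k = 4) {
  p <- k * tau_peak; q <- k * (1 - tau_peak)
  peak <- tau_peak^p * (1 - tau_peak)^q
  tau^p * (1 - tau)^q / peak
}

#' Noiseless muscle activation envelopes for one trial
#'
#' Each muscle's envelope is a smooth non-negative activation bump over
#' the trial, peaking at the muscle's characteristic normalized time
#' (`tau_peak` in the ground truth's `muscle_profile`) with peak
#' amplitude `path_gain * (a0 + a1 * mass_g)`; muscles with `a1 = 0`
#' (posterior deltoid by default) are mass-independent, and the
#' direction-dependent `path_gain` captures the different recruitment of
#' elbow and shoulder muscles when carrying leftward versus rightward.
#' The raw EMG synthesizer later modulates a 30--400 Hz noise carrier
#' with this envelope.
#'
#' @param trial List or one-row data frame with at least `t_start_s`,
#'   `t_end_s`, `path` and `mass_g`.
#' @param truth A [ground_truth()].
#' @param fs_hz Sampling rate of the returned envelopes.
#' @return Matrix muscles x samples spanning the trial.
#' @export
generate_muscle_activity <- function(trial, truth, fs_hz = 1000) {
  dur <- trial$t_end_s - trial$t_start_s
  if (dur <= 0) stop_invalid("trial must have t_end_s > t_start_s")
  if (trial$mass_g < 0) stop_invalid("mass_g must be non-negative")
  amp <- truth$muscle_mass_coeffs[, "a0"] +
    truth$muscle_mass_coeffs[, "a1"] * trial$mass_g
  if (any(amp < 0))
    stop_invalid("negative envelope amplitude for mass %g g", trial$mass_g)
  prof <- truth$muscle_profile
  pg <- if (identical(trial$path, 2L) || identical(trial$path, 2))
    prof$path2_gain else prof$path1_gain
  n <- round(dur * fs_hz) + 1L
  tau <- seq(0, 1, length.out = n)
  out <- t(vapply(seq_along(amp), function(mch)
    amp[mch] * pg[mch] * activation_bump(tau, prof$tau_peak[mch]),
    numeric(n)))
  rownames(out) <- rownames(truth$muscle_mass_coeffs)
  out
}

# 1/f amplitude-shaped Gaussian noise, standardized to unit sd
pink_noise <- function(n) {
  m <- stats::nextn(n, 2)
  w <- stats::fft(rnorm(m))
  f <- c(1, seq_len(m - 1L))
  f <- pmin(f, m - f + 1)          # symmetric frequency index
  shaped <- Re(stats::fft(w / sqrt(f), inverse = TRUE)) / m
  shaped <- shaped[seq_len(n)]
  (shaped - mean(shaped)) / sd(shaped)
}

# band-limited unit-variance noise carrier
band_carrier <- function(n, fs, edges) {
  x <- butter_bandpass(rnorm(n), fs, edges[1], edges[2], order = 4L)
  x / sd(x)
}

#' Generate a complete synthetic session
#'
#' Builds a continuous recording of alternating path-1/path-2 carrying
#' trials, grouped in blocks by object mass, with inter-trial rest.  Every
#' ECoG channel is a sum of band-limited carriers amplitude-modulated by
#' its ground-truth drivers (object position/speed for extrinsic channels,
#' muscle envelopes for intrinsic ones), an additive low-frequency
#' position component on extrinsic channels, and 1/f plus white noise.
#' Raw EMG is a 30--400 Hz noise carrier modulated by the activation
#' envelope; object motion is the arc trajectory sampled at the motion
#' rate plus small Gaussian jitter (sd 2 mm).
#'
#' @param cfg A [task_config()].
#' @param truth A [ground_truth()]; defaults to [default_ground_truth()].
#' @return List of class `ecog_session` with elements `ecog` (channels x
#'   samples), `emg` (muscles x samples), `motion` (data frame t/X/Y/Z),
#'   `events` (data frame trial_id/t_start_s/t_end_s/path/mass_g), `meta`
#'   (channel names, grid coordinates, regions, sampling rates) and
#'   `truth`.
#' @export
generate_session <- function(cfg = task_config(),
                             truth = default_ground_truth(cfg)) {
  n_ch <- cfg$grid_rows * cfg$grid_cols
  if (length(truth$channel_class) != n_ch)
    stop_invalid("ground truth describes %d channels but the grid has %d",
                 length(truth$channel_class), n_ch)
  if (nrow(truth$couplings) && max(truth$couplings$channel) > n_ch)
    stop_invalid("coupling refers to a channel outside the grid")
  set.seed(cfg$seed)
  fs <- cfg$fs_ecog_hz
  lead_in <- max(1.5, cfg$inter_trial_s)   # >= 1 s so a 100 x 0.01 s lag window fits
  # -- schedule ---------------------------------------------------------
  ev <- list(); tcur <- lead_in; id <- 0L
  for (mass in cfg$masses_g) {
    for (rep_i in seq_len(cfg$n_trials_per_mass)) {
      for (p in c(1L, 2L)) {
        id <- id + 1L
        dur <- cfg$trial_duration_s * runif(1, 0.95, 1.05)
        ev[[id]] <- data.frame(trial_id = id, t_start_s = tcur,
                               t_end_s = tcur + dur, path = p, mass_g = mass)
        tcur <- tcur + dur + cfg$inter_trial_s
      }
    }
  }
  events <- do.call(rbind, ev)
  total_s <- tcur + 0.5
  N <- as.integer(ceiling(total_s * fs))
  tgrid <- (seq_len(N) - 1L) / fs

  # -- kinematic drivers at the ECoG rate -------------------------------
  pos <- matrix(0, N, 3L, dimnames = list(NULL, c("X", "Y", "Z")))
  pos[, "X"] <- 200                       # resting at the path-1 start point
  for (k in seq_len(nrow(events))) {
    i0 <- as.integer(round(events$t_start_s[k] * fs)) + 1L
    dur <- events$t_end_s[k] - events$t_start_s[k]
    traj <- generate_trajectory(events$path[k], dur, cfg$lift_height_mm, fs)
    idx <- i0:(i0 + nrow(traj) - 1L)
    pos[idx, ] <- as.matrix(traj[, c("X", "Y", "Z")])
    if (k < nrow(events)) {               # hold the end point through rest
      nxt <- as.integer(round(events$t_start_s[k + 1L] * fs))
      if (nxt > max(idx)) pos[(max(idx) + 1L):nxt, ] <-
          matrix(pos[max(idx), ], nxt - max(idx), 3L, byrow = TRUE)
    } else if (max(idx) < N) {
      pos[(max(idx) + 1L):N, ] <- matrix(pos[max(idx), ], N - max(idx), 3L,
                                         byrow = TRUE)
    }
  }
  speed <- c(0, sqrt(rowSums(diff(pos)^2)) * fs)

  # -- muscle envelopes -------------------------------------------------
  musc <- matrix(0, 4L, N, dimnames = list(emg_muscles(), NULL))
  for (k in seq_len(nrow(events))) {
    env_k <- generate_muscle_activity(events[k, ], truth, fs)
    i0 <- as.integer(round(events$t_start_s[k] * fs)) + 1L
    musc[, i0:(i0 + ncol(env_k) - 1L)] <- env_k
  }

  to01 <- function(x) if (diff(range(x)) == 0) x * 0 else
    (x - min(x)) / diff(range(x))
  drivers01 <- rbind(pos_x = to01(pos[, "X"]), pos_y = to01(pos[, "Y"]),
                     speed = to01(speed),
                     sweep(musc, 1L, pmax(apply(musc, 1L, max), .Machine$double.eps), "/"))

  # -- ECoG -------------------------------------------------------------
  bands <- ecog_bands()
  ecog <- matrix(0, n_ch, N)
  for (ch in seq_len(n_ch)) {
    sig <- numeric(N)
    cp <- truth$couplings[truth$couplings$channel == ch, , drop = FALSE]
    for (b in unique(cp$band)) {
      rows <- cp[cp$band == b, , drop = FALSE]
      modulation <- rep(1, N)
      for (r in seq_len(nrow(rows)))
        modulation <- modulation + rows$gain[r] * drivers01[rows$driver[r], ]
      sig <- sig + band_carrier(N, fs, bands[[b]]) * modulation
    }
    if (nrow(truth$lowfreq)) {
      lf <- truth$lowfreq[truth$lowfreq$channel == ch, , drop = FALSE]
      for (r in seq_len(nrow(lf))) {
        ref <- if (lf$driver[r] == "pos_x") pos[, "X"] / 200 else pos[, "Y"] / 150
        sig <- sig + lf$gain[r] * ref
      }
    }
    if (truth$pink_sd > 0) sig <- sig + truth$pink_sd * pink_noise(N)
    if (truth$white_sd > 0) sig <- sig + truth$white_sd * rnorm(N)
    ecog[ch, ] <- sig
  }

  # -- raw EMG ----------------------------------------------------------
  emg <- matrix(0, 4L, N, dimnames = list(emg_muscles(), NULL))
  for (mch in 1:4) {
    carrier <- band_carrier(N, cfg$fs_emg_hz, c(30, 400))
    floor_sd <- 0.01 * max(max(musc[mch, ]), .Machine$double.eps)
    emg[mch, ] <- musc[mch, ] * carrier + floor_sd * rnorm(N)
  }

  # -- motion at the camera rate ----------------------------------------
  t30 <- seq(0, tgrid[N], by = 1 / cfg$fs_motion_hz)
  i30 <- pmin(as.integer(round(t30 * fs)) + 1L, N)
  motion <- data.frame(t = t30,
                       X = pos[i30, "X"] + rnorm(length(i30), 0, 2),
                       Y = pos[i30, "Y"] + rnorm(length(i30), 0, 2),
                       Z = pos[i30, "Z"] + rnorm(length(i30), 0, 2))

  grid_row <- rep(seq_len(cfg$grid_rows), each = cfg$grid_cols)
  grid_col <- rep(seq_len(cfg$grid_cols), times = cfg$grid_rows)
  meta <- list(channel = sprintf("ch%02d", seq_len(n_ch)),
               grid_row = grid_row, grid_col = grid_col,
               x_mm = (grid_col - 1L) * cfg$pitch_mm,
               y_mm = (grid_row - 1L) * cfg$pitch_mm,
               region = truth$region,
               fs_ecog_hz = fs, fs_emg_hz = cfg$fs_emg_hz,
               fs_motion_hz = cfg$fs_motion_hz,
               muscles = emg_muscles())
  rownames(ecog) <- meta$channel
  structure(list(ecog = ecog, emg = emg, motion = motion, events = events,
                 meta = meta, truth = truth, config = cfg),
            class = "ecog_session")
}

#' @export
print.ecog_session <- function(x, ...) {
  cat(sprintf("ecog_session: %d channels x %d samples at %g Hz, %d trials (%s g), %d muscles\n",
              nrow(x$ecog), ncol(x$ecog), x$meta$fs_ecog_hz, nrow(x$events),
              paste(unique(x$events$mass_g), collapse = "/"), nrow(x$emg)))
  invisible(x)
}
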
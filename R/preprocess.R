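#' Canonical ECoG frequency bands
#'
#' The nine band-pass edges used to decompose ECoG before envelope
#' extraction: delta 0.1--4, theta 4--8, alpha 8--14, beta1 14--20,
#' beta2 20--30, gamma1 30--60, gamma2 60--90, gamma3 90--120 and
#' gamma4 120--150 Hz.  The delta band is implemented as a 0.1--4 Hz
#' band-pass so that DC drift is suppressed while slow cortical
#' potentials are retained.
#'
#' @return Named list of length-2 numeric vectors `c(low, high)` in Hz.
#' @export
ecog_bands <- function() {
  list(
    delta  = c(0.1, 4),
    theta  = c(4, 8),
    alpha  = c(8, 14),
    beta1  = c(14, 20),
    beta2  = c(20, 30),
    gamma1 = c(30, 60),
    gamma2 = c(60, 90),
    gamma3 = c(90, 120),
    gamma4 = c(120, 150)
  )
}

#' Common average reference
#'
#' Subtracts the cross-channel mean from every channel at each sample.
#'
#' @param x Numeric matrix, channels x samples.
#' @return Matrix of the same shape with zero cross-channel mean at every
#'   sample.
#' @export
common_average_reference <- function(x) {
  if (!is.matrix(x) || nrow(x) < 2L)
    stop_invalid("common average reference requires a matrix with >= 2 channels")
  sweep(x, 2L, colMeans(x), "-")
}

# zero-phase Butterworth band-pass; `order` is the overall filter order of the
# band-pass (must be even: a band-pass of order 2k comes from a k-th order
# low-pass prototype)
butter_bandpass <- function(x, fs, low, high, order = 4L, zero_phase = TRUE) {
  if (order %% 2L != 0L) stop_invalid("band-pass `order` must be even")
  bt <- signal::butter(order %/% 2L, c(low, high) / (fs / 2), type = "pass")
  if (zero_phase) signal::filtfilt(bt, x) else as.numeric(signal::filter(bt, x))
}

#' Band-pass filter bank
#'
#' Decomposes each channel into the nine canonical frequency bands with
#' fourth-order Butterworth band-pass filters, applied forward-backward
#' (zero phase) by default.
#'
#' @param x Numeric matrix, channels x samples (a single channel may be
#'   passed as a vector).
#' @param fs Sampling rate in Hz; must exceed 300 Hz so that the top band
#'   edge (150 Hz) is below Nyquist.
#' @param bands Named list of band edges, see [ecog_bands()].
#' @param order Overall band-pass filter order (default 4).
#' @param zero_phase Apply forward-backward filtering (default `TRUE`).
#' @return A 3-d array channels x bands x samples, with band names on the
#'   second dimension.
#' @export
bandpass_filterbank <- function(x, fs, bands = ecog_bands(), order = 4L,
                                zero_phase = TRUE) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  check_scalar_pos(fs, "fs")
  top <- max(vapply(bands, max, numeric(1)))
  if (fs <= 2 * top)
    stop_invalid("fs = %g Hz is too low for a %g Hz band edge", fs, top)
  out <- array(0, dim = c(nrow(x), length(bands), ncol(x)),
               dimnames = list(rownames(x), names(bands), NULL))
  for (ch in seq_len(nrow(x))) {
    for (b in seq_along(bands)) {
      out[ch, b, ] <- butter_bandpass(x[ch, ], fs, bands[[b]][1], bands[[b]][2],
                                      order = order, zero_phase = zero_phase)
    }
  }
  out
}

# unit-area Gaussian kernel truncated at +/- 4 sigma
gaussian_kernel <- function(sigma_s, fs) {
  half <- max(1L, ceiling(4 * sigma_s * fs))
  t <- (-half:half) / fs
  k <- exp(-t^2 / (2 * sigma_s^2))
  k / sum(k)
}

# centred convolution with edge replication so that a constant signal is
# mapped to itself
gaussian_smooth <- function(x, sigma_s, fs) {
  k <- gaussian_kernel(sigma_s, fs)
  half <- (length(k) - 1L) %/% 2L
  xp <- c(rep(x[1L], half), x, rep(x[length(x)], half))
  y <- stats::filter(xp, k, method = "convolution", sides = 2L)
  as.numeric(y[(half + 1L):(half + length(x))])
}

#' Band envelope features
#'
#' Turns band-limited components into slow amplitude features: optional
#' full-wave rectification, smoothing with a unit-area Gaussian window
#' (time constant `sigma_s`, truncated at four standard deviations), and
#' decimation to `out_fs` (every `fs/out_fs`-th sample kept; the Gaussian
#' window is the anti-alias stage).
#'
#' @param banded 3-d array channels x bands x samples as produced by
#'   [bandpass_filterbank()].
#' @param fs Input sampling rate in Hz; must be an integer multiple of
#'   `out_fs`.
#' @param rectify Take the absolute value before smoothing (default `TRUE`);
#'   with `rectify = FALSE` the band-pass signal itself is smoothed and
#'   down-sampled (the "unrectified" feature variant).
#' @param sigma_s Gaussian time constant in seconds (default 0.04).
#' @param out_fs Output rate in Hz (default 100).
#' @return 3-d array channels x bands x samples at `out_fs`.
#' @export
envelope_features <- function(banded, fs, rectify = TRUE, sigma_s = 0.04,
                              out_fs = 100) {
  stopifnot(is.array(banded), length(dim(banded)) == 3L)
  dec <- fs / out_fs
  if (abs(dec - round(dec)) > 1e-9)
    stop_invalid("fs = %g is not an integer multiple of out_fs = %g", fs, out_fs)
  dec <- as.integer(round(dec))
  n_out <- ((dim(banded)[3L] - 1L) %/% dec) + 1L
  keep <- seq(1L, by = dec, length.out = n_out)
  out <- array(0, dim = c(dim(banded)[1L], dim(banded)[2L], n_out),
               dimnames = c(dimnames(banded)[1:2], list(NULL)))
  for (ch in seq_len(dim(banded)[1L])) {
    for (b in seq_len(dim(banded)[2L])) {
      s <- banded[ch, b, ]
      if (rectify) s <- abs(s)
      out[ch, b, ] <- gaussian_smooth(s, sigma_s, fs)[keep]
    }
  }
  out
}

#' Extract the band-envelope feature tensor from raw ECoG
#'
#' Runs the full ECoG feature pipeline: common average reference, nine-band
#' Butterworth filter bank, full-wave rectification (for the rectified
#' variant), Gaussian smoothing and down-sampling to 100 Hz.  Feature `i`
#' enumerates `(channel, band, variant)`; with both variants and `n`
#' electrodes there are `n x 9 x 2` features.
#'
#' @param ecog Numeric matrix, channels x samples.
#' @param fs Sampling rate of `ecog` in Hz.
#' @param variants Character subset of `c("rectified", "unrectified")`.
#' @param bands Band edges, see [ecog_bands()].
#' @param sigma_s Gaussian smoothing time constant in seconds.
#' @param out_fs Feature rate in Hz (default 100).
#' @param car Apply the common average reference first (default `TRUE`).
#' @param order,zero_phase Filter-bank settings, see [bandpass_filterbank()].
#' @return A `feature_tensor`: list with `values` (features x samples),
#'   `key` (data.frame channel / band / variant per feature row), `fs`,
#'   `band_edges`, `n_channels` and `stats` (`NULL` until z-scored).
#' @export
ecog_features <- function(ecog, fs, variants = c("rectified", "unrectified"),
                          bands = ecog_bands(), sigma_s = 0.04, out_fs = 100,
                          car = TRUE, order = 4L, zero_phase = TRUE) {
  variants <- match.arg(variants, c("rectified", "unrectified"),
                        several.ok = TRUE)
  if (car) ecog <- common_average_reference(ecog)
  n_ch <- nrow(ecog)
  n_b <- length(bands)
  dec <- as.integer(round(fs / out_fs))
  n_out <- ((ncol(ecog) - 1L) %/% dec) + 1L
  vals <- matrix(0, n_ch * n_b * length(variants), n_out)
  key <- data.frame(channel = integer(0), band = character(0),
                    variant = character(0), stringsAsFactors = FALSE)
  row <- 0L
  for (ch in seq_len(n_ch)) {
    banded <- bandpass_filterbank(ecog[ch, , drop = FALSE], fs, bands,
                                  order = order, zero_phase = zero_phase)
    for (v in variants) {
      env <- envelope_features(banded, fs, rectify = (v == "rectified"),
                               sigma_s = sigma_s, out_fs = out_fs)
      for (b in seq_len(n_b)) {
        row <- row + 1L
        vals[row, ] <- env[1L, b, ]
        key[row, ] <- list(ch, names(bands)[b], v)
      }
    }
  }
  structure(list(values = vals, key = key, fs = out_fs, band_edges = bands,
                 n_channels = n_ch, stats = NULL),
            class = "feature_tensor")
}

#' @export
print.feature_tensor <- function(x, ...) {
  cat(sprintf("feature_tensor: %d features (%d channels x %d bands x %d variants), %d samples at %g Hz%s\n",
              nrow(x$values), x$n_channels, length(x$band_edges),
              length(unique(x$key$variant)), ncol(x$values), x$fs,
              if (is.null(x$stats)) "" else ", z-scored"))
  invisible(x)
}

#' Z-score normalization of a feature tensor
#'
#' Standardizes every feature to `z_i(t) = (x_i(t) - mu_i) / sigma_i` where
#' `mu_i` and `sigma_i` are the per-feature mean and sample standard
#' deviation (denominator `n - 1`).  The statistics are computed over
#' `fit_idx` (default: all samples) and stored in the result so they can be
#' reapplied to held-out data; pass `stats` to reuse statistics from a
#' training fit.
#'
#' @param ft A `feature_tensor` (or bare features x samples matrix).
#' @param stats Optional precomputed list with `mu` and `sd` per feature.
#' @param fit_idx Optional integer sample indices over which to compute the
#'   statistics (e.g. samples belonging to training trials).
#' @return The tensor with normalized `values` and the `stats` used.
#' @export
zscore_features <- function(ft, stats = NULL, fit_idx = NULL) {
  bare <- !inherits(ft, "feature_tensor")
  x <- if (bare) ft else ft$values
  if (is.null(stats)) {
    idx <- if (is.null(fit_idx)) seq_len(ncol(x)) else fit_idx
    if (length(idx) < 2L)
      stop_invalid("need >= 2 samples to estimate normalization statistics")
    mu <- rowMeans(x[, idx, drop = FALSE])
    sdv <- apply(x[, idx, drop = FALSE], 1L, sd)
    stats <- list(mu = mu, sd = sdv)
  }
  bad <- which(!is.finite(stats$sd) | stats$sd <= 0)
  if (length(bad))
    stop_invalid("degenerate feature(s) with zero variance: %s",
                 paste(head(bad, 5L), collapse = ", "))
  z <- (x - stats$mu) / stats$sd
  if (bare) return(z)
  ft$values <- z
  ft$stats <- stats
  ft
}

#' EMG envelope estimation
#'
#' Standard surface-EMG activation envelope: 30--400 Hz band-pass
#' (second-order Butterworth, zero phase), full-wave rectification,
#' second-order low-pass at 2.2 Hz (zero phase), then down-sampling
#' to 100 Hz.
#'
#' @param raw_emg Numeric matrix, muscles x samples (vector allowed for a
#'   single muscle).
#' @param fs Sampling rate in Hz; must be at least 800 Hz so the 400 Hz
#'   band edge is reachable, and an integer multiple of `out_fs`.
#' @param band Band-pass edges in Hz (default `c(30, 400)`).
#' @param lp_hz Smoothing low-pass cutoff in Hz (default 2.2).
#' @param out_fs Output rate (default 100).
#' @return List of class `envelope_series` with `values` (muscles x samples
#'   at `out_fs`), `fs` and `muscles` (row names of the input, if any).
#' @export
emg_envelope <- function(raw_emg, fs, band = c(30, 400), lp_hz = 2.2,
                         out_fs = 100) {
  if (is.vector(raw_emg)) raw_emg <- matrix(raw_emg, nrow = 1L)
  if (fs < 2 * band[2]) stop_invalid("fs = %g Hz too low for a %g Hz band edge",
                                     fs, band[2])
  dec <- fs / out_fs
  if (abs(dec - round(dec)) > 1e-9)
    stop_invalid("fs must be an integer multiple of out_fs")
  dec <- as.integer(round(dec))
  lp <- signal::butter(2L, lp_hz / (fs / 2), type = "low")
  n_out <- ((ncol(raw_emg) - 1L) %/% dec) + 1L
  keep <- seq(1L, by = dec, length.out = n_out)
  vals <- matrix(0, nrow(raw_emg), n_out)
  for (mch in seq_len(nrow(raw_emg))) {
    s <- butter_bandpass(raw_emg[mch, ], fs, band[1], band[2], order = 2L)
    s <- abs(s)
    s <- signal::filtfilt(lp, s)
    vals[mch, ] <- s[keep]
  }
  structure(list(values = vals, fs = out_fs, muscles = rownames(raw_emg)),
            class = "envelope_series")
}
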
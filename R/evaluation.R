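#' Root-mean-square error and Pearson correlation
#'
#' The two accuracy metrics used for decoder evaluation.  RMSE is in the
#' units of the target (mm for coordinates, a.u. for muscle activity);
#' CC is the Pearson product-moment correlation.
#'
#' @param actual,predicted Equal-length numeric vectors (length >= 2).
#' @param allow_degenerate If `TRUE`, a zero-variance series yields
#'   `cc = NA` instead of an error (used by cross-validation, where a
#'   fully pruned decoder predicts a constant).
#' @return List with `rmse` and `cc`.
#' @export
decoding_metrics <- function(actual, predicted, allow_degenerate = FALSE) {
  if (length(actual) != length(predicted) || length(actual) < 2L)
    stop_invalid("actual and predicted must have equal length >= 2")
  if (!all(is.finite(actual)) || !all(is.finite(predicted)))
    stop_invalid("non-finite values in the series")
  rmse <- sqrt(mean((actual - predicted)^2))
  if (sd(actual) == 0 || sd(predicted) == 0) {
    if (!allow_degenerate)
      stop_invalid("correlation undefined: a series has zero variance")
    cc <- NA_real_
  } else {
    cc <- stats::cor(actual, predicted)
  }
  list(rmse = rmse, cc = cc)
}

#' Resample one trial onto a normalized-time grid
#'
#' Linear interpolation of a within-trial series onto `n_points` equally
#' spaced points of normalized time tau in [0, 1]; the endpoints are
#' preserved.  Trials of different durations become comparable on this
#' grid.
#'
#' @param x Numeric vector over one trial (>= 2 samples).
#' @param n_points Grid size (default 200).
#' @return Numeric vector of length `n_points`.
#' @export
resample_trial <- function(x, n_points = 200L) {
  if (length(x) < 2L) stop_invalid("a trial needs at least 2 samples")
  tau_in <- seq(0, 1, length.out = length(x))
  approx(tau_in, x, xout = seq(0, 1, length.out = n_points))$y
}

#' One-way ANOVA at selected normalized time points
#'
#' Compares trial values across mass groups at each requested normalized
#' time with a standard one-way fixed-effects ANOVA.
#'
#' @param resampled Numeric matrix, trials x grid points (each row a trial
#'   resampled with [resample_trial()]).
#' @param groups Grouping vector (e.g. object mass) of length `nrow(resampled)`.
#' @param taus Normalized time points to test (default 0.25, 0.5, 0.75).
#' @return Data frame with columns `tau`, `F`, `df1`, `df2`, `p`.
#' @export
anova_timepoints <- function(resampled, groups, taus = c(0.25, 0.5, 0.75)) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop_invalid("need >= 2 groups")
  if (any(table(groups) < 2L)) stop_invalid("every group needs >= 2 trials")
  n_grid <- ncol(resampled)
  out <- lapply(taus, function(tau) {
    j <- round(tau * (n_grid - 1L)) + 1L
    ht <- oneway.test(resampled[, j] ~ groups, var.equal = TRUE)
    data.frame(tau = tau, F = unname(ht$statistic),
               df1 = unname(ht$parameter[1L]), df2 = unname(ht$parameter[2L]),
               p = ht$p.value)
  })
  do.call(rbind, out)
}

# feature-sample indices (at rate fs) falling inside trial k's half-open
# interval [t_start, t_end)
trial_sample_idx <- function(events, k, fs, n_samples) {
  i0 <- as.integer(ceiling(events$t_start_s[k] * fs - 1e-9)) + 1L
  i1 <- as.integer(ceiling(events$t_end_s[k] * fs - 1e-9))   # last t < t_end
  i0:min(i1, n_samples)
}

#' Decoding targets of a session at the feature rate
#'
#' Builds the seven decodable target series at 100 Hz: object X, Y and Z
#' coordinates (motion cubic-interpolated from the camera rate) and the
#' four muscle activation envelopes (via [emg_envelope()]).
#'
#' @param session An `ecog_session`.
#' @param out_fs Target rate (default 100 Hz).
#' @return List with `t` (time axis) and one numeric series per target
#'   (`x`, `y`, `z`, `biceps`, `triceps`, `deltoid_ant`, `deltoid_post`),
#'   all aligned with the ECoG feature tensor.
#' @export
session_targets <- function(session, out_fs = 100) {
  dec <- session$meta$fs_ecog_hz / out_fs
  n100 <- ((ncol(session$ecog) - 1L) %/% as.integer(round(dec))) + 1L
  t100 <- (seq_len(n100) - 1L) / out_fs
  out <- list(t = t100)
  for (axis in c("X", "Y", "Z"))
    out[[tolower(axis)]] <- spline(session$motion$t, session$motion[[axis]],
                                   xout = t100, method = "natural")$y
  env <- emg_envelope(session$emg, session$meta$fs_emg_hz, out_fs = out_fs)
  for (mch in seq_along(session$meta$muscles))
    out[[session$meta$muscles[mch]]] <- env$values[mch, seq_len(n100)]
  out
}

#' Decoder settings
#'
#' Bundles the lag-embedding and fitter parameters.  The defaults are the
#' reference analysis constants: `m = 100` lags spaced `dt_s = 0.01` s
#' (a 1 s history per feature) on z-scored features at 100 Hz, with both
#' rectified and unrectified feature variants and normalization statistics
#' computed from training trials only.
#'
#' @param m Number of lags per feature.
#' @param dt_s Lag spacing in seconds.
#' @param row_stride Stride (in feature samples) between design rows used
#'   for fitting; 1 uses every sample.  Prediction always uses every
#'   sample of the evaluated trials.
#' @param variants Feature variants to include.
#' @param zscore_scope `"training"` (statistics from training trials only,
#'   leakage-free; the default) or `"session"` (whole-session statistics).
#' @param tol,max_iter,prune_alpha Fitter controls, see [fit_slir()].
#' @return List of class `decoder_config`.
#' @export
decoder_config <- function(m = 100L, dt_s = 0.01, row_stride = 1L,
                           variants = c("rectified", "unrectified"),
                           zscore_scope = c("training", "session"),
                           tol = 1e-6, max_iter = 500L, prune_alpha = 1e3) {
  structure(list(m = as.integer(m), dt_s = dt_s,
                 row_stride = as.integer(row_stride),
                 variants = match.arg(variants,
                                      c("rectified", "unrectified"),
                                      several.ok = TRUE),
                 zscore_scope = match.arg(zscore_scope),
                 tol = tol, max_iter = max_iter, prune_alpha = prune_alpha),
            class = "decoder_config")
}

# restrict a feature tensor to the requested variants
filter_variants <- function(ft, variants) {
  keep <- ft$key$variant %in% variants
  if (!all(keep)) {
    ft$values <- ft$values[keep, , drop = FALSE]
    ft$key <- ft$key[keep, , drop = FALSE]
    rownames(ft$key) <- NULL
    if (!is.null(ft$stats))
      ft$stats <- list(mu = ft$stats$mu[keep], sd = ft$stats$sd[keep])
  }
  ft
}

# z-score a raw tensor with statistics from the samples of `stat_trials`,
# build a fitting design over strided samples of `fit_trials` and fit
fit_trials_slir <- function(ft_raw, target, events, fit_trials, config,
                            stats = NULL) {
  n_s <- ncol(ft_raw$values)
  fs <- ft_raw$fs
  if (is.null(stats)) {
    stat_idx <- sort(unique(unlist(lapply(fit_trials, function(k)
      trial_sample_idx(events, k, fs, n_s)))))
    if (config$zscore_scope == "session") stat_idx <- NULL
    ftz <- zscore_features(ft_raw, fit_idx = stat_idx)
  } else {
    ftz <- zscore_features(ft_raw, stats = stats)
  }
  fit_rows <- unlist(lapply(fit_trials, function(k) {
    idx <- trial_sample_idx(events, k, fs, n_s)
    idx[seq(1L, length(idx), by = config$row_stride)]
  }))
  design <- build_lagged_design(ftz, rows = fit_rows, m = config$m,
                                dt_s = config$dt_s)
  model <- fit_slir(design, target[design$rows], tol = config$tol,
                    max_iter = config$max_iter,
                    prune_alpha = config$prune_alpha)
  model$fingerprint <- config_hash(unclass(config))
  list(model = model, ftz = ftz, stats = ftz$stats)
}

# predict every sample of `trials` with a fitted model
predict_trials <- function(model, ftz, target, events, trials, config) {
  n_s <- ncol(ftz$values)
  lapply(trials, function(k) {
    idx <- trial_sample_idx(events, k, ftz$fs, n_s)
    design <- build_lagged_design(ftz, rows = idx, m = config$m,
                                  dt_s = config$dt_s)
    list(trial_id = events$trial_id[k], idx = design$rows,
         actual = target[design$rows], predicted = predict(model, design))
  })
}

#' Leave-one-trial-out cross-validation of a decoder
#'
#' For each trial, fits the sparse decoder on every other trial's samples
#' (normalization statistics recomputed from the training trials when
#' `zscore_scope = "training"`), predicts the held-out trial at the full
#' feature rate, and records per-trial RMSE and CC.  Pooled metrics are
#' reported both over the concatenated held-out predictions and as the
#' mean of per-trial values; trials whose prediction or target is constant
#' have undefined CC, are recorded as `NA` and excluded from means (their
#' count is reported; when no fold has a defined CC the mean absolute CC
#' is reported as 0, since a constant predictor carries no linear
#' association).
#'
#' @param ft_raw Raw (un-normalized) `feature_tensor` of the session.
#' @param target Numeric target series aligned with the feature samples.
#' @param events The session's trial table.
#' @param config A [decoder_config()].
#' @param trials Integer indices (into `events`) of the trials to
#'   cross-validate; default all.
#' @return List of class `cv_result`: `per_trial` (data.frame `trial_id`,
#'   `mass_g`, `path`, `rmse`, `cc`), `pooled_rmse`, `pooled_cc`
#'   (concatenated residuals), `mean_rmse`, `mean_cc`, `mean_abs_cc`,
#'   `n_cc_excluded`, `predictions` (per fold) and `config`.
#' @export
decode_loocv <- function(ft_raw, target, events, config = decoder_config(),
                         trials = seq_len(nrow(events))) {
  if (length(trials) < 3L) stop_invalid("leave-one-out needs >= 3 trials")
  ft_raw <- filter_variants(ft_raw, config$variants)
  folds <- vector("list", length(trials))
  for (fi in seq_along(trials)) {
    k <- trials[fi]
    train <- setdiff(trials, k)
    fit <- fit_trials_slir(ft_raw, target, events, train, config)
    pred <- predict_trials(fit$model, fit$ftz, target, events, k, config)[[1L]]
    met <- decoding_metrics(pred$actual, pred$predicted,
                            allow_degenerate = TRUE)
    folds[[fi]] <- list(pred = pred, rmse = met$rmse, cc = met$cc,
                        n_active = sum(fit$model$active))
  }
  per_trial <- data.frame(
    trial_id = events$trial_id[trials],
    mass_g = events$mass_g[trials],
    path = events$path[trials],
    rmse = vapply(folds, `[[`, numeric(1), "rmse"),
    cc = vapply(folds, function(f) as.numeric(f$cc), numeric(1)))
  all_actual <- unlist(lapply(folds, function(f) f$pred$actual))
  all_pred <- unlist(lapply(folds, function(f) f$pred$predicted))
  pooled <- decoding_metrics(all_actual, all_pred, allow_degenerate = TRUE)
  valid <- !is.na(per_trial$cc)
  structure(list(
    per_trial = per_trial,
    pooled_rmse = pooled$rmse, pooled_cc = pooled$cc,
    mean_rmse = mean(per_trial$rmse),
    mean_cc = if (any(valid)) mean(per_trial$cc[valid]) else NA_real_,
    mean_abs_cc = if (any(valid)) mean(abs(per_trial$cc[valid])) else 0,
    n_cc_excluded = sum(!valid),
    predictions = lapply(folds, `[[`, "pred"),
    config = config), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: %d folds, pooled RMSE %.4g, pooled CC %.3f, mean |CC| %.3f (%d folds with undefined CC)\n",
              nrow(x$per_trial), x$pooled_rmse, x$pooled_cc, x$mean_abs_cc,
              x$n_cc_excluded))
  invisible(x)
}
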
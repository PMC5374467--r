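#' Fit a decoder on a set of trials
#'
#' Convenience wrapper that z-scores the raw feature tensor (statistics
#' from the fitted trials, or the whole session, per the configured
#' scope), builds the lag-embedded design over the fitted trials and runs
#' [fit_slir()].
#'
#' @param ft_raw Raw `feature_tensor`.
#' @param target Target series aligned with the feature samples.
#' @param events Trial table.
#' @param config A [decoder_config()].
#' @param trials Trials to fit on (default all).
#' @return List with `model` (a `slir_model`), `ftz` (the z-scored tensor,
#'   restricted to the configured variants), `stats` (normalization
#'   statistics for reuse on held-out data), `events` and `config`.
#' @export
fit_decoder <- function(ft_raw, target, events, config = decoder_config(),
                        trials = seq_len(nrow(events))) {
  ft_raw <- filter_variants(ft_raw, config$variants)
  fit <- fit_trials_slir(ft_raw, target, events, trials, config)
  list(model = fit$model, ftz = fit$ftz, stats = fit$stats,
       events = events, config = config)
}

# per-column channel / band / variant labels for a model fitted on a
# lag-embedded design built from `feature_key`
column_labels <- function(model, feature_key) {
  if (is.null(model$column_key)) {
    if (length(model$w) != nrow(feature_key))
      stop_invalid("model carries no column key and its size does not match the feature key")
    model$column_key <- data.frame(feature = seq_len(nrow(feature_key)),
                                   lag = 0L)
  }
  fi <- model$column_key$feature
  data.frame(channel = feature_key$channel[fi],
             band = feature_key$band[fi],
             variant = feature_key$variant[fi],
             lag = model$column_key$lag,
             stringsAsFactors = FALSE)
}

#' Normalized electrode weight map
#'
#' Normalizes every weight magnitude by the global maximum,
#' `|w_ij| / |w_max|`, and aggregates per channel (sum of normalized
#' magnitudes over bands, variants and lags) and per channel-variant,
#' reproducing the rectified/unrectified map panels.
#'
#' @param model A fitted `slir_model`.
#' @param feature_key The `key` data frame of the feature tensor the model
#'   was trained on (one row per feature: channel, band, variant).
#' @param meta Optional session `meta` list (grid coordinates for
#'   rendering).
#' @return List of class `weight_map`: `entries` (data.frame channel /
#'   band / variant / lag / w / norm), `w_max_abs`, `per_channel`,
#'   `per_channel_variant`, `all_zero` flag and `meta`.
#' @export
weight_map <- function(model, feature_key, meta = NULL) {
  lab <- column_labels(model, feature_key)
  w <- model$w
  w_max <- max(abs(w))
  all_zero <- w_max == 0
  if (all_zero) {
    warning("all weights are zero; the map is all-zero")
    norm <- abs(w)
  } else {
    norm <- abs(w) / w_max
  }
  entries <- cbind(lab, w = w, norm = norm)
  per_channel <- tapply(entries$norm, entries$channel, sum)
  pcv <- stats::aggregate(norm ~ channel + variant, data = entries, FUN = sum)
  structure(list(entries = entries, w_max_abs = w_max,
                 per_channel = per_channel, per_channel_variant = pcv,
                 all_zero = all_zero, meta = meta),
            class = "weight_map")
}

#' @export
print.weight_map <- function(x, ...) {
  cat(sprintf("weight_map: %d entries over %d channels, |w_max| = %.4g%s\n",
              nrow(x$entries), length(x$per_channel), x$w_max_abs,
              if (x$all_zero) " (all zero)" else ""))
  invisible(x)
}

#' Render a weight map on the electrode grid
#'
#' @param x A `weight_map` whose `meta` holds `grid_row` / `grid_col`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.weight_map <- function(x, ...) {
  if (is.null(x$meta)) stop_invalid("no grid metadata attached to the map")
  rows <- x$meta$grid_row; cols <- x$meta$grid_col
  z <- matrix(NA_real_, max(rows), max(cols))
  agg <- x$per_channel
  for (ch in seq_along(rows)) z[rows[ch], cols[ch]] <- agg[as.character(ch)]
  graphics::image(t(z)[, rev(seq_len(nrow(z))), drop = FALSE],
                  axes = FALSE, xlab = "grid column", ylab = "grid row", ...)
  invisible(x)
}

#' Frequency-band weight shares
#'
#' The share of total absolute weight carried by each frequency band,
#' `share(b) = sum |w| in band b / sum |w|`; shares sum to 1.  Also
#' reported split by feature variant.
#'
#' @param model A fitted `slir_model` with at least one nonzero weight.
#' @param feature_key Feature key of the training tensor.
#' @return List with `by_band` (named shares) and `by_band_variant`
#'   (data.frame band / variant / share).
#' @export
band_weight_ratio <- function(model, feature_key) {
  lab <- column_labels(model, feature_key)
  total <- sum(abs(model$w))
  if (total == 0) stop_invalid("weight ratio undefined: all weights are zero")
  by_band <- c(tapply(abs(model$w), lab$band, sum)) / total
  by_band[is.na(by_band)] <- 0
  bv <- stats::aggregate(list(share = abs(model$w) / total),
                         by = list(band = lab$band, variant = lab$variant),
                         FUN = sum)
  list(by_band = by_band, by_band_variant = bv)
}

#' Compare normalized weights between cortical regions
#'
#' Two-sample t-test comparing the populations of normalized weight
#' magnitudes of channels labelled with one region against another
#' (premotor vs primary motor by default).  The population is per-feature
#' (every band, variant and lag entry) by default; `aggregate =
#' "channel"` tests the per-channel sums instead.
#'
#' @param wmap A [weight_map()].
#' @param regions Character vector of region labels per channel (from the
#'   session `meta`).
#' @param pair Two region labels to compare (default `c("PM", "M1")`).
#' @param aggregate `"feature"` (default) or `"channel"`.
#' @param var_equal Student's equal-variance test (default `TRUE`);
#'   `FALSE` gives Welch.
#' @return List of class `stat_result`: `statistic` (t), `df`, `p`,
#'   `group_means`, `group_sizes`, `pair`.
#' @export
region_ttest <- function(wmap, regions, pair = c("PM", "M1"),
                         aggregate = c("feature", "channel"),
                         var_equal = TRUE) {
  aggregate <- match.arg(aggregate)
  if (!all(pair %in% regions))
    stop_invalid("region(s) %s absent from the metadata",
                 paste(setdiff(pair, regions), collapse = ", "))
  pick <- function(reg) {
    chs <- which(regions == reg)
    if (aggregate == "feature")
      wmap$entries$norm[wmap$entries$channel %in% chs]
    else
      unname(wmap$per_channel[as.character(chs)])
  }
  g1 <- pick(pair[1L]); g2 <- pick(pair[2L])
  if (length(g1) < 2L || length(g2) < 2L)
    stop_invalid("both regions need >= 2 observations")
  ht <- t.test(g1, g2, var.equal = var_equal)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p = ht$p.value,
                 group_means = c(mean(g1), mean(g2)),
                 group_sizes = c(length(g1), length(g2)),
                 pair = pair), class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("t(%0.4g) = %.4g, p = %.4g (%s mean %.4g vs %s mean %.4g)\n",
              x$df, x$statistic, x$p, x$pair[1L], x$group_means[1L],
              x$pair[2L], x$group_means[2L]))
  invisible(x)
}

#' Mass-transfer matrix of single-mass decoders
#'
#' Evaluates decoders trained on one object mass on every mass condition.
#' Each training mass contributes its family of leave-one-trial-out fold
#' decoders: diagonal entries pool each fold decoder's error on its own
#' held-out trial (exactly the within-mass LOO result), and off-diagonal
#' entries pool the same fold decoders' errors on all trials of the test
#' mass (no refitting; each fold's training-mass normalization statistics
#' are applied to the test data).  Using the same decoders on both sides
#' makes the comparison a pure data-transfer contrast.  When several
#' target series are supplied (e.g. X and Y coordinates, one decoder
#' each) the RMSE pools their residuals.
#'
#' @param ft_raw Raw `feature_tensor`.
#' @param targets Named list of target series.
#' @param events Trial table.
#' @param config A [decoder_config()].
#' @param masses Mass conditions (default: unique masses in `events`).
#' @return List of class `transfer_matrix`: `rmse` (train x test matrix),
#'   `per_target` (list of matrices), `masses`, `config`.
#' @export
transfer_matrix <- function(ft_raw, targets, events,
                            config = decoder_config(),
                            masses = sort(unique(events$mass_g))) {
  if (!is.list(targets)) targets <- list(target = targets)
  ft_raw <- filter_variants(ft_raw, config$variants)
  fp <- config_hash(unclass(config))
  n_m <- length(masses)
  sq_sum <- matrix(0, n_m, n_m, dimnames = list(train = masses, test = masses))
  n_obs <- matrix(0, n_m, n_m)
  per_target <- lapply(targets, function(...)
    matrix(NA_real_, n_m, n_m, dimnames = list(train = masses, test = masses)))
  for (a in seq_len(n_m)) {
    trials_a <- which(events$mass_g == masses[a])
    if (length(trials_a) < 3L)
      stop_invalid("mass %s has fewer than 3 trials", masses[a])
    for (tg in names(targets)) {
      y <- targets[[tg]]
      res2 <- vector("list", n_m)       # pooled squared residuals per test mass
      for (fi in seq_along(trials_a)) {
        fit <- fit_trials_slir(ft_raw, y, events, trials_a[-fi], config)
        if (!identical(fit$model$fingerprint, fp))
          stop_invalid("decoder configuration mismatch across masses")
        for (b in seq_len(n_m)) {
          test_trials <- if (b == a) trials_a[fi] else
            which(events$mass_g == masses[b])
          preds <- predict_trials(fit$model, fit$ftz, y, events, test_trials,
                                  config)
          res2[[b]] <- c(res2[[b]], unlist(lapply(preds, function(p)
            (p$actual - p$predicted)^2)))
        }
      }
      for (b in seq_len(n_m)) {
        per_target[[tg]][a, b] <- sqrt(mean(res2[[b]]))
        sq_sum[a, b] <- sq_sum[a, b] + sum(res2[[b]])
        n_obs[a, b] <- n_obs[a, b] + length(res2[[b]])
      }
    }
  }
  structure(list(rmse = sqrt(sq_sum / n_obs), per_target = per_target,
                 masses = masses, config = config),
            class = "transfer_matrix")
}

#' @export
print.transfer_matrix <- function(x, ...) {
  cat("transfer_matrix (RMSE, rows = training mass, columns = test mass):\n")
  print(round(x$rmse, 4))
  invisible(x)
}

# per-channel prediction components (no bias): rows x channels matrix whose
# row sums plus w0 equal the full prediction
channel_predictions <- function(model, design, feature_key) {
  lab <- column_labels(model, feature_key)
  channels <- sort(unique(feature_key$channel))
  out <- matrix(0, nrow(design$X), length(channels),
                dimnames = list(NULL, channels))
  for (ci in seq_along(channels)) {
    cols <- which(lab$channel == channels[ci] & model$w != 0)
    if (length(cols))
      out[, ci] <- drop(design$X[, cols, drop = FALSE] %*% model$w[cols])
  }
  out
}

#' Single-channel contribution to the between-mass difference
#'
#' Quantifies how much each electrode contributes to the predicted
#' difference between two mass conditions.  The full-model prediction is
#' trial-averaged on the 200-point normalized-time grid for each mass of
#' the pair; the per-channel predictions (that channel's weights only, no
#' bias) are averaged the same way.  Each channel's contribution is the
#' mean of its between-mass difference curve over the normalized-time
#' window (default tau in [0.4, 0.6]), expressed as a percentage of the
#' full-model mean difference over the same window.  Because the model is
#' linear and the bias cancels in differences, the signed percentages sum
#' to exactly 100.
#'
#' @param fit A [fit_decoder()] result (model trained on all masses and
#'   paths, plus the z-scored tensor).
#' @param mass_pair Two masses; the difference is `second - first`
#'   (default `c(25, 500)`).
#' @param path Which path's trials to use (1 or 2).
#' @param window Normalized-time window (default `c(0.4, 0.6)`), endpoints
#'   inclusive.
#' @param n_points Normalized-time grid size (default 200).
#' @return List of class `contribution_map`: `per_channel` (data.frame
#'   channel / mean_diff / percent), `full_mean_diff`, `tau`,
#'   `full_diff_curve`, `channel_diff_curves` (channels x grid),
#'   `mass_pair`, `path`, `window`.
#' @export
contribution_map <- function(fit, mass_pair = c(25, 500), path = 1,
                             window = c(0.4, 0.6), n_points = 200L) {
  events <- fit$events; model <- fit$model; ftz <- fit$ftz
  config <- fit$config
  tau <- seq(0, 1, length.out = n_points)
  sel <- tau >= window[1L] - 1e-12 & tau <= window[2L] + 1e-12
  channels <- sort(unique(ftz$key$channel))
  avg_curves <- function(mass) {
    trials <- which(events$mass_g == mass & events$path == path)
    if (!length(trials))
      stop_invalid("no trials with mass %g g on path %d", mass, path)
    full_acc <- numeric(n_points)
    ch_acc <- matrix(0, length(channels), n_points)
    for (k in trials) {
      idx <- trial_sample_idx(events, k, ftz$fs, ncol(ftz$values))
      design <- build_lagged_design(ftz, rows = idx, m = config$m,
                                    dt_s = config$dt_s)
      full <- predict(model, design)
      chp <- channel_predictions(model, design, ftz$key)
      full_acc <- full_acc + resample_trial(full, n_points)
      for (ci in seq_along(channels))
        ch_acc[ci, ] <- ch_acc[ci, ] + resample_trial(chp[, ci], n_points)
    }
    list(full = full_acc / length(trials), chan = ch_acc / length(trials))
  }
  lo <- avg_curves(mass_pair[1L])
  hi <- avg_curves(mass_pair[2L])
  full_diff <- hi$full - lo$full
  chan_diff <- hi$chan - lo$chan
  denom <- mean(full_diff[sel])
  if (abs(denom) < 1e-9)
    stop_invalid("contribution undefined: full-model mean difference %.3g is below 1e-9",
                 denom)
  mean_diff <- rowMeans(chan_diff[, sel, drop = FALSE])
  per_channel <- data.frame(channel = channels, mean_diff = mean_diff,
                            percent = 100 * mean_diff / denom)
  structure(list(per_channel = per_channel, full_mean_diff = denom,
                 tau = tau, full_diff_curve = full_diff,
                 channel_diff_curves = chan_diff,
                 mass_pair = mass_pair, path = path, window = window),
            class = "contribution_map")
}

#' @export
print.contribution_map <- function(x, ...) {
  top <- x$per_channel[order(-abs(x$per_channel$percent)), ][1:3, ]
  cat(sprintf("contribution_map (%g vs %g g, path %d, tau %.2f-%.2f): top channels %s\n",
              x$mass_pair[1L], x$mass_pair[2L], x$path, x$window[1L],
              x$window[2L],
              paste(sprintf("ch%02d %.1f%%", top$channel, top$percent),
                    collapse = ", ")))
  invisible(x)
}
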
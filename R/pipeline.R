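#' Full analysis configuration
#'
#' All pipeline parameters with their reference defaults: the nine
#' canonical band edges, Gaussian smoothing time constant 0.04 s (the
#' nominal 3.98 Hz cutoff of that window is recorded as metadata), ECoG
#' features at 1000 -> 100 Hz, EMG band 30--400 Hz smoothed at 2.2 Hz,
#' and a decoder with `m = 100` lags spaced 0.01 s.
#'
#' @param decoder A [decoder_config()].
#' @param ecog_fs_hz,feature_fs_hz ECoG input and feature rates.
#' @param bands Band edges, see [ecog_bands()].
#' @param gaussian_sigma_s Smoothing time constant in seconds.
#' @param emg_band_hz,emg_lp_hz EMG band-pass edges and smoothing cutoff.
#' @return List of class `pipeline_config` with a `hash` fingerprint.
#' @export
pipeline_config <- function(decoder = decoder_config(),
                            ecog_fs_hz = 1000, feature_fs_hz = 100,
                            bands = ecog_bands(), gaussian_sigma_s = 0.04,
                            emg_band_hz = c(30, 400), emg_lp_hz = 2.2) {
  cfg <- list(decoder = decoder, ecog_fs_hz = ecog_fs_hz,
              feature_fs_hz = feature_fs_hz, bands = bands,
              gaussian_sigma_s = gaussian_sigma_s,
              gaussian_cutoff_hz = 3.98,   # nominal, metadata only
              emg_band_hz = emg_band_hz, emg_lp_hz = emg_lp_hz)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "pipeline_config")
}

#' Run the end-to-end decoding analysis on a session
#'
#' Orchestrates feature extraction, per-target decoder training,
#' leave-one-trial-out cross-validation, weight and band-ratio analysis
#' with the region t-test, the mass-transfer matrix and the
#' single-channel contribution analysis, writing tab-separated / JSON
#' outputs and a manifest to `out_dir`.  Every output records the
#' configuration hash; two runs with identical session and configuration
#' produce identical bundles.
#'
#' @param session An `ecog_session`.
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param targets Target names to decode (subset of those returned by
#'   [session_targets()]).
#' @param stages Analysis stages to run after training.
#' @param contrib_masses,contrib_path Settings for the contribution stage.
#' @return List of class `pipeline_result` with the per-stage objects.
#' @export
run_pipeline <- function(session, config = pipeline_config(), out_dir = NULL,
                         targets = c("x", "y", "biceps"),
                         stages = c("loocv", "weights", "transfer", "contrib"),
                         contrib_masses = c(25, 500), contrib_path = 1) {
  stages <- match.arg(stages, several.ok = TRUE)
  ft <- ecog_features(session$ecog, session$meta$fs_ecog_hz,
                      variants = config$decoder$variants,
                      bands = config$bands,
                      sigma_s = config$gaussian_sigma_s,
                      out_fs = config$feature_fs_hz)
  tg <- session_targets(session, out_fs = config$feature_fs_hz)
  res <- list(config = config, targets = targets, fits = list(),
              loocv = list())
  for (t_name in targets) {
    y <- tg[[t_name]]
    if (is.null(y)) stop_invalid("unknown target `%s`", t_name)
    res$fits[[t_name]] <- fit_decoder(ft, y, session$events, config$decoder)
    if ("loocv" %in% stages)
      res$loocv[[t_name]] <- decode_loocv(ft, y, session$events,
                                          config$decoder)
  }
  if ("weights" %in% stages) {
    res$weight_maps <- lapply(res$fits, function(f)
      weight_map(f$model, f$ftz$key, session$meta))
    res$band_ratios <- lapply(res$fits, function(f)
      band_weight_ratio(f$model, f$ftz$key))
    res$region_tests <- lapply(res$weight_maps, region_ttest,
                               regions = session$meta$region)
  }
  if ("transfer" %in% stages) {
    traj <- intersect(targets, c("x", "y", "z"))
    if (length(traj))
      res$transfer <- transfer_matrix(ft, tg[traj], session$events,
                                      config$decoder)
  }
  if ("contrib" %in% stages) {
    muscle <- intersect(targets, session$meta$muscles)
    if (length(muscle))
      res$contribution <- contribution_map(res$fits[[muscle[1L]]],
                                           mass_pair = contrib_masses,
                                           path = contrib_path)
  }
  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(res, session, out_dir)
  res
}

write_pipeline_outputs <- function(res, session, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- res$config$hash
  if (length(res$loocv)) {
    cv <- do.call(rbind, lapply(names(res$loocv), function(t_name)
      cbind(target = t_name, res$loocv[[t_name]]$per_trial)))
    data.table::fwrite(cv, file.path(out_dir, "cv_results.tsv"), sep = "\t")
    summ <- lapply(res$loocv, function(cv)
      list(pooled_rmse = cv$pooled_rmse, pooled_cc = cv$pooled_cc,
           mean_rmse = cv$mean_rmse, mean_cc = cv$mean_cc,
           n_cc_excluded = cv$n_cc_excluded))
    jsonlite::write_json(list(config_hash = hash, targets = summ),
                         file.path(out_dir, "cv_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(res$weight_maps)) {
    wm <- do.call(rbind, lapply(names(res$weight_maps), function(t_name) {
      agg <- res$weight_maps[[t_name]]$per_channel
      data.frame(target = t_name, channel = as.integer(names(agg)),
                 aggregate = as.numeric(agg))
    }))
    data.table::fwrite(wm, file.path(out_dir, "weight_map.tsv"), sep = "\t")
    br <- do.call(rbind, lapply(names(res$band_ratios), function(t_name)
      cbind(target = t_name, res$band_ratios[[t_name]]$by_band_variant)))
    data.table::fwrite(br, file.path(out_dir, "band_ratios.tsv"), sep = "\t")
    jsonlite::write_json(
      list(config_hash = hash,
           tests = lapply(res$region_tests, function(s)
             list(t = s$statistic, df = s$df, p = s$p,
                  means = s$group_means))),
      file.path(out_dir, "region_test.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(res$transfer)) {
    tm <- as.data.frame(res$transfer$rmse)
    tm <- cbind(train_mass = rownames(tm), tm)
    data.table::fwrite(tm, file.path(out_dir, "transfer_rmse.tsv"),
                       sep = "\t")
  }
  if (!is.null(res$contribution))
    data.table::fwrite(res$contribution$per_channel,
                       file.path(out_dir, "contribution.tsv"), sep = "\t")
  manifest <- list(config_hash = hash,
                   package_version = as.character(utils::packageVersion("ecogdecode")),
                   n_trials = nrow(session$events),
                   n_channels = nrow(session$ecog),
                   targets = res$targets,
                   n_bands = length(res$config$bands),
                   m = res$config$decoder$m, dt_s = res$config$decoder$dt_s)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
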
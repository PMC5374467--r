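#' Write a session directory
#'
#' Serializes an `ecog_session` to plain-text files: `ecog.csv` (one
#' column per channel), `emg.csv`, `motion.csv` (t, X, Y, Z),
#' `events.tsv` (trial_id, t_start_s, t_end_s, path, mass_g) and
#' `meta.json` (sampling rates, channel names, grid coordinates, region
#' labels, and the ground-truth block when the session is synthetic).
#' Times are in seconds throughout; trial intervals are half-open
#' `[t_start, t_end)`.
#'
#' @param session An `ecog_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data.table::as.data.table(t(session$ecog)),
                     file.path(dir, "ecog.csv"))
  data.table::fwrite(data.table::as.data.table(t(session$emg)),
                     file.path(dir, "emg.csv"))
  data.table::fwrite(session$motion, file.path(dir, "motion.csv"))
  data.table::fwrite(session$events, file.path(dir, "events.tsv"), sep = "\t")
  meta <- session$meta
  if (!is.null(session$truth)) {
    tr <- session$truth
    meta$ground_truth <- list(
      channel_class = tr$channel_class, region = tr$region,
      couplings = tr$couplings, lowfreq = tr$lowfreq,
      muscle_mass_coeffs = as.data.frame(tr$muscle_mass_coeffs),
      muscle = rownames(tr$muscle_mass_coeffs),
      pink_sd = tr$pink_sd, white_sd = tr$white_sd)
  }
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a session directory
#'
#' Loads and validates a session written by [write_session()] (or
#' assembled by hand in the same layout).  Trial events are checked
#' against the recording span and each other; region labels must come
#' from the allowed set.
#'
#' @param dir Session directory.
#' @return An `ecog_session`.
#' @export
read_session <- function(dir) {
  need <- c("ecog.csv", "emg.csv", "motion.csv", "events.tsv", "meta.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing))
    stop_invalid("session directory is missing: %s",
                 paste(missing, collapse = ", "))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  ecog <- t(as.matrix(data.table::fread(file.path(dir, "ecog.csv"))))
  emg <- t(as.matrix(data.table::fread(file.path(dir, "emg.csv"))))
  motion <- as.data.frame(data.table::fread(file.path(dir, "motion.csv")))
  events <- as.data.frame(data.table::fread(file.path(dir, "events.tsv")))
  if (!all(meta$region %in% c("PM", "M1", "other")))
    stop_invalid("meta.json: unknown region label(s): %s",
                 paste(setdiff(meta$region, c("PM", "M1", "other")),
                       collapse = ", "))
  if (length(meta$channel) != nrow(ecog))
    stop_invalid("meta.json names %d channels but ecog.csv has %d",
                 length(meta$channel), nrow(ecog))
  # align channel order to the metadata by name
  cn <- rownames(ecog)
  if (!setequal(cn, meta$channel))
    stop_invalid("ecog.csv channel names do not match meta.json")
  ecog <- ecog[match(meta$channel, cn), , drop = FALSE]
  rownames(ecog) <- meta$channel
  span <- (ncol(ecog) - 1L) / meta$fs_ecog_hz
  bad <- which(events$t_end_s <= events$t_start_s)
  if (length(bad))
    stop_invalid("events.tsv row %d: t_end_s <= t_start_s", bad[1L])
  out_of_span <- which(events$t_start_s < 0 | events$t_end_s > span)
  if (length(out_of_span))
    stop_invalid("events.tsv row %d: trial outside the recording span (%.2f s)",
                 out_of_span[1L], span)
  truth <- NULL
  if (!is.null(meta$ground_truth)) {
    gt <- meta$ground_truth
    mmc <- as.matrix(gt$muscle_mass_coeffs)
    rownames(mmc) <- gt$muscle
    truth <- ground_truth(gt$channel_class, gt$region,
                          as.data.frame(gt$couplings),
                          as.data.frame(gt$lowfreq), mmc,
                          pink_sd = gt$pink_sd, white_sd = gt$white_sd)
    meta$ground_truth <- NULL
  }
  rownames(emg) <- meta$muscles
  structure(list(ecog = ecog, emg = emg, motion = motion, events = events,
                 meta = meta, truth = truth, config = NULL),
            class = "ecog_session")
}
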
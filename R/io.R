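#' Write a session to a directory of plain-text tables
#'
#' Layout: `spikes.tsv` (cell_id, t), `position.tsv` (t, x, y),
#' `lfp<k>.tsv` (one column of samples per channel) and `metadata.tsv`
#' (flat key/value). Floating values are written with 12 significant
#' digits so a round trip is lossless at analysis precision.
#'
#' @param session a `ps_session`.
#' @param path directory to create/overwrite.
#' @export
write_session <- function(session, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create ", path)
  fmt <- function(x) formatC(x, digits = 12, format = "g")
  sp <- session$spikes
  sp$t <- fmt(sp$t)
  utils::write.table(sp, file.path(path, "spikes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  po <- session$position
  po$t <- fmt(po$t); po$x <- fmt(po$x); po$y <- fmt(po$y)
  utils::write.table(po, file.path(path, "position.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (k in seq_along(session$lfp)) {
    ch <- session$lfp[[k]]
    utils::write.table(data.frame(v = fmt(ch$samples)),
                       file.path(path, sprintf("lfp%d.tsv", k)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  meta <- c(trial_kind = session$trial_kind,
            duration_s = fmt(session$duration),
            age_days = as.character(session$age_days),
            n_lfp = as.character(length(session$lfp)),
            fs_lfp = paste(fmt(vapply(session$lfp, `[[`, 0, "fs")),
                           collapse = ","))
  if (!is.null(session$track))
    meta <- c(meta, side_cm = fmt(session$track$side_cm),
              track_width_cm = fmt(session$track$width_cm),
              linearization_step_cm = fmt(session$track$step_cm))
  utils::write.table(data.frame(key = names(meta), value = unname(meta)),
                     file.path(path, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Read a session written by [write_session()]
#'
#' @param path session directory.
#' @return a validated `ps_session`.
#' @export
read_session <- function(path) {
  need <- c("spikes.tsv", "position.tsv", "metadata.tsv")
  miss <- need[!file.exists(file.path(path, need))]
  if (length(miss)) stop("missing required table(s): ",
                         paste(miss, collapse = ", "))
  meta_df <- utils::read.table(file.path(path, "metadata.tsv"), sep = "\t",
                               header = TRUE, colClasses = "character")
  meta <- stats::setNames(meta_df$value, meta_df$key)
  sp <- utils::read.table(file.path(path, "spikes.tsv"), sep = "\t",
                          header = TRUE,
                          colClasses = c(cell_id = "integer", t = "numeric"))
  bad <- which(!is.finite(sp$t) | is.na(sp$cell_id))
  if (length(bad)) stop("unparseable spike rows at line(s): ",
                        paste(bad + 1L, collapse = ", "))
  po <- utils::read.table(file.path(path, "position.tsv"), sep = "\t",
                          header = TRUE, colClasses = "numeric")
  lfp <- list()
  n_lfp <- as.integer(meta[["n_lfp"]])
  if (n_lfp > 0) {
    fs <- as.numeric(strsplit(meta[["fs_lfp"]], ",")[[1]])
    for (k in seq_len(n_lfp)) {
      v <- utils::read.table(file.path(path, sprintf("lfp%d.tsv", k)),
                             sep = "\t", header = TRUE)$v
      lfp[[k]] <- list(samples = as.numeric(v), fs = fs[k])
    }
  }
  track <- NULL
  if ("side_cm" %in% names(meta))
    track <- track_geometry(side_cm = as.numeric(meta[["side_cm"]]),
                            width_cm = as.numeric(meta[["track_width_cm"]]),
                            step_cm = as.numeric(meta[["linearization_step_cm"]]))
  ps_session(trial_kind = meta[["trial_kind"]], spikes = sp, position = po,
             lfp = lfp, duration = as.numeric(meta[["duration_s"]]),
             track = track, age_days = as.integer(meta[["age_days"]]))
}

#' Default analysis configuration
#'
#' Every threshold used by the pipeline, at the values used throughout:
#' immobility floor 2.5 cm/s, 2.5 cm spatial bins, adaptive-smoothing
#' alpha 200, 5 cm track kernel, 1.6/0.8 s state windows, theta 5-11 Hz,
#' delta 1.5-4 Hz, ripple band 100-250 Hz with 7 ms RMS and 99th-percentile
#' threshold, 100 ms SWR windows, MUA 1 ms bins / 10 ms Gaussian / 3 SD /
#' 100-750 ms duration, replay decode 20/10 ms, 25 cm band, slopes 0-2500
#' step 50 cm/s, 500 shuffles at the 95th percentile, ensemble gate
#' (>25 cells, >75 RUN spikes, <10 cm median online error in 300 ms
#' windows), awake pause limit 1 cm/s, theta decoding 20/5 ms with 10
#' theta-time bins and a 10.6 cm/s target median speed, field bounds at
#' 20%/50% of peak, precession gates SI > 0.15 and > 25 field spikes.
#'
#' @param ... overrides by name.
#' @export
ps_config <- function(...) {
  cfg <- list(
    speed_floor = 2.5, bin_cm = 2.5, alpha = 200, sigma_cm = 5,
    min_bout_s = 5, linearization_step_cm = 0.25,
    state_window_s = 1.6, state_step_s = 0.8, state_ratio = 2, state_nw = 2.5,
    theta_band = c(5, 11), delta_band = c(1.5, 4),
    ripple_band = c(100, 250), rms_window_s = 0.007, swr_percentile = 0.99,
    swr_window_s = 0.1,
    mua_bin_s = 0.001, mua_sigma_s = 0.010, mua_sd = 3,
    mua_duration_s = c(0.100, 0.750),
    replay_window_s = 0.020, replay_step_s = 0.010,
    band_cm = 25, slope_max = 2500, slope_step = 50,
    n_shuffles = 500, shuffle_method = "cell_id", significance_percentile = 0.95,
    min_spikes_run = 75, min_ensemble_cells = 25,
    max_online_decode_median_error = 10, online_window_s = 0.300,
    awake_speed_limit = 1,
    theta_window_s = 0.020, theta_step_s = 0.005, n_theta_bins = 10,
    target_median_speed = 10.6, rel_pos_extent_cm = 50,
    field_edge_frac = 0.20, field_minimum_frac = 0.50,
    min_spatial_information = 0.15, min_field_spikes = 25,
    rate_floor_hz = 0.01)
  ov <- list(...)
  stopifnot(all(names(ov) %in% names(cfg)))
  cfg[names(ov)] <- ov
  cfg
}
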
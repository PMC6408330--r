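#' Best linear trajectory band through a decoded posterior
#'
#' Maximizes the summed posterior probability inside a 25 cm wide band
#' around the line `pos(t) = start + slope * t`, over starts every 2.5 cm
#' along the track and signed slopes -2500..2500 cm/s in 50 cm/s steps
#' (speeds are reported as |slope|). Bands wrap circularly around the
#' track. Ties are broken toward lower |slope|, then lower start.
#'
#' @param posterior n_windows x n_bins matrix from [decode_event()].
#' @param t_mid window centre times (s).
#' @param bin_cm spatial bin size (cm).
#' @param cfg [ps_config()] supplying `band_cm`, `slope_max`, `slope_step`.
#' @return list `score`, `slope` (signed cm/s), `speed` = |slope|,
#'   `start_pos` (cm), `n_windows`.
#' @export
fit_linear_band <- function(posterior, t_mid, bin_cm = 2.5,
                            cfg = ps_config()) {
  if (nrow(posterior) < 3) return(NULL)   # too short to fit
  slopes_abs <- seq(0, cfg$slope_max, by = cfg$slope_step)
  slopes <- unique(as.vector(rbind(slopes_abs, -slopes_abs)))  # |s| ascending
  trel <- t_mid - t_mid[1]
  half_band <- floor((cfg$band_cm / 2) / bin_cm)
  r <- .band_best_fit(posterior, trel, slopes, bin_cm, as.integer(half_band))
  list(score = r$score, slope = r$slope, speed = abs(r$slope),
       start_pos = (r$start_bin - 0.5) * bin_cm, n_windows = nrow(posterior))
}

#' Shuffle significance of a candidate event's linear fit
#'
#' The event is decoded and fitted against both direction maps; the real
#' score is the best across directions. The null population re-decodes and
#' re-fits the event `n_shuffles` times with either cell identities
#' permuted against the rate maps (`"cell_id"`) or each map circularly
#' offset by an independent random amount (`"map"`); CW and CCW sets are
#' shuffled independently and each shuffle contributes its best fit across
#' directions. The event is significant when the real score exceeds the
#' 95th percentile of the shuffle scores.
#'
#' @param spikes event spikes (`cell_id`, `t`).
#' @param cell_ids ensemble cell order.
#' @param t_start,t_end event bounds.
#' @param F_cw,F_ccw decoding matrices (n_bins x n_cells).
#' @param cfg [ps_config()].
#' @return list `fit` (best real fit + direction), `p_shuffle`,
#'   `significant`, `shuffle_scores`, or `NULL` when the event is too short.
#' @export
shuffle_significance <- function(spikes, cell_ids, t_start, t_end,
                                 F_cw, F_ccw, cfg = ps_config()) {
  wc <- window_counts(spikes, cell_ids, t_start, t_end,
                      cfg$replay_window_s, cfg$replay_step_s)
  if (ncol(wc$counts) < 3) return(NULL)
  tau <- cfg$replay_window_s
  bin_cm <- cfg$bin_cm
  fit_one <- function(F) {
    post <- bayes_decode(wc$counts, F, tau)
    fit_linear_band(post, wc$t_mid, bin_cm, cfg)
  }
  f_cw <- fit_one(F_cw); f_ccw <- fit_one(F_ccw)
  real <- if (f_cw$score >= f_ccw$score) c(f_cw, direction = "CW")
          else c(f_ccw, direction = "CCW")
  nc <- length(cell_ids)
  nb <- nrow(F_cw)
  shuf <- numeric(cfg$n_shuffles)
  if (cfg$n_shuffles < 100) warning("fewer than 100 shuffles: wide CI")
  use_map <- switch(cfg$shuffle_method, cell_id = FALSE, map = TRUE,
                    stop("unknown shuffle method"))
  slopes_abs <- seq(0, cfg$slope_max, by = cfg$slope_step)
  slopes <- unique(as.vector(rbind(slopes_abs, -slopes_abs)))
  trel <- wc$t_mid - wc$t_mid[1]
  half_band <- as.integer(floor((cfg$band_cm / 2) / bin_cm))
  counts <- matrix(as.numeric(wc$counts), nrow(wc$counts))
  lF_cw <- log(F_cw); lF_ccw <- log(F_ccw)
  for (s in seq_len(cfg$n_shuffles)) {
    best <- -Inf
    for (d in 1:2) {   # CW and CCW shuffled independently
      perm <- if (use_map) integer(nc) else sample.int(nc)
      off <- if (use_map) sample.int(nb, nc, replace = TRUE) - 1L
             else integer(nc)
      lF <- if (d == 1) lF_cw else lF_ccw
      F <- if (d == 1) F_cw else F_ccw
      best <- max(best, .shuffle_fit_score(lF, F, counts, tau, trel, slopes,
                                           bin_cm, half_band, perm, off,
                                           use_map))
    }
    shuf[s] <- best
  }
  p <- mean(shuf >= real$score)
  thr <- stats::quantile(shuf, cfg$significance_percentile, names = FALSE)
  list(fit = real, p_shuffle = p, significant = real$score > thr,
       shuffle_scores = shuf)
}

#' Run the replay pipeline over a rest (or awake-pause) session
#'
#' Detects SWRs and MUA bursts, keeps SWR-coincident bursts as candidate
#' events, decodes each with 20/10 ms windows against both direction maps,
#' fits linear bands and computes the 500-shuffle significance. Replay
#' speed is |slope| of the best fit and distance = speed x MUA duration.
#'
#' @param session rest `ps_session` with LFP.
#' @param F_cw,F_ccw decoding matrices.
#' @param cell_ids ensemble cell order.
#' @param cfg [ps_config()].
#' @param epochs optional data.frame of epochs to which candidate events
#'   are restricted (e.g. awake pauses); `NULL` uses the whole session.
#' @param seed per-session base seed; event k is shuffled with seed
#'   `seed + k` for reproducibility.
#' @return data.frame: one row per candidate event with `t_start`, `t_end`,
#'   `duration`, `slope`, `speed`, `distance`, `start_pos`, `score`,
#'   `direction`, `p_shuffle`, `significant`.
#' @export
replay_pipeline <- function(session, F_cw, F_ccw, cell_ids,
                            cfg = ps_config(), epochs = NULL, seed = 1L) {
  swr <- detect_swr(session$lfp, cfg)
  mua <- detect_mua(session$spikes, session$duration, cfg)
  ev <- joint_events(mua, swr)
  if (!is.null(epochs) && nrow(ev))
    ev <- ev[in_epochs(ev$t_start, epochs) & in_epochs(ev$t_end, epochs), ,
             drop = FALSE]
  score_events(ev, session$spikes, cell_ids, F_cw, F_ccw, cfg, seed)
}

#' Decode, fit and test a table of candidate events
#'
#' The scoring core of [replay_pipeline()], usable directly on candidate
#' events constructed elsewhere (e.g. synthetic null events).
#'
#' @param events data.frame with `t_start`, `t_end`.
#' @param spikes session spikes.
#' @inheritParams replay_pipeline
#' @export
score_events <- function(events, spikes, cell_ids, F_cw, F_ccw,
                         cfg = ps_config(), seed = 1L) {
  out <- list()
  for (k in seq_len(nrow(events))) {
    t0 <- events$t_start[k]; t1 <- events$t_end[k]
    sp <- spikes[spikes$t >= t0 & spikes$t < t1, , drop = FALSE]
    set.seed(seed + k)
    r <- shuffle_significance(sp, cell_ids, t0, t1, F_cw, F_ccw, cfg)
    if (is.null(r)) next
    out[[length(out) + 1]] <- data.frame(
      t_start = t0, t_end = t1, duration = t1 - t0,
      slope = r$fit$slope, speed = r$fit$speed,
      distance = r$fit$speed * (t1 - t0),
      start_pos = r$fit$start_pos, score = r$fit$score,
      direction = r$fit$direction, p_shuffle = r$p_shuffle,
      significant = r$significant, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(t_start = numeric(), t_end = numeric(),
                      duration = numeric(), slope = numeric(),
                      speed = numeric(), distance = numeric(),
                      start_pos = numeric(), score = numeric(),
                      direction = character(), p_shuffle = numeric(),
                      significant = logical()))
  do.call(rbind, out)
}

#' Session-level replay summary
#'
#' Proportion of candidate events with a significant linear trajectory
#' (with Clopper-Pearson 95% CI and an exact binomial test against the 5%
#' chance rate), and mean +/- SEM of trajectory speed and distance over the
#' significant events (stationary slope-0 events included).
#'
#' @param results data.frame from [replay_pipeline()].
#' @export
session_replay_summary <- function(results) {
  n <- nrow(results)
  stopifnot(n >= 1)
  k <- sum(results$significant)
  ci <- binomial_proportion_ci(k, n)
  sig <- results[results$significant, , drop = FALSE]
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  list(n_events = n, n_significant = k,
       prop_significant = ci$p_hat, ci_lo = ci$lo, ci_hi = ci$hi,
       p_binomial = ci$p_value,
       mean_speed = if (k) mean(sig$speed) else NA_real_,
       sem_speed = if (k > 1) sem(sig$speed) else NA_real_,
       mean_distance = if (k) mean(sig$distance) else NA_real_,
       sem_distance = if (k > 1) sem(sig$distance) else NA_real_)
}

#' Awake replay during RUN pauses
#'
#' The identical replay machinery applied to the RUN session, with
#' candidate events restricted to non-locomotor epochs (speed < 1 cm/s).
#'
#' @param run_session unfiltered track RUN `ps_session` with LFP.
#' @inheritParams replay_pipeline
#' @export
awake_replay <- function(run_session, F_cw, F_ccw, cell_ids,
                         cfg = ps_config(), seed = 1L) {
  sp <- speed_estimate(run_session)
  pauses <- runs_to_epochs(sp < cfg$awake_speed_limit, run_session$position$t)
  if (nrow(pauses) == 0)
    return(score_events(data.frame(t_start = numeric(), t_end = numeric()),
                        run_session$spikes, cell_ids, F_cw, F_ccw, cfg, seed))
  replay_pipeline(run_session, F_cw, F_ccw, cell_ids, cfg,
                  epochs = pauses, seed = seed)
}

#' Ensemble inclusion gate for replay analysis
#'
#' An ensemble qualifies when more than `min_ensemble_cells` complex-spike
#' cells fired more than `min_spikes_run` spikes during RUN (after
#' immobility filtering) and the online decoding median error is below
#' `max_online_decode_median_error`.
#'
#' @param run_session immobility-filtered RUN session.
#' @param median_error from [online_decode_error()].
#' @param cfg [ps_config()].
#' @return list `pass`, `cell_ids` (cells passing the spike-count filter),
#'   `n_cells`, `median_error`.
#' @export
ensemble_gate <- function(run_session, median_error, cfg = ps_config()) {
  counts <- table(run_session$spikes$cell_id)
  ids <- as.integer(names(counts)[counts > cfg$min_spikes_run])
  list(pass = length(ids) > cfg$min_ensemble_cells &&
              median_error < cfg$max_online_decode_median_error,
       cell_ids = sort(ids), n_cells = length(ids),
       median_error = median_error)
}
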
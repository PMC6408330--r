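#' Weighted circular-linear correlation
#'
#' `rcl = sqrt((rXC^2 + rXS^2 - 2 rXC rXS rCS) / (1 - rCS^2))` where rXC,
#' rXS and rCS are (optionally weighted) Pearson correlations between the
#' linear variable and cos/sin of the angular variable, and between the two
#' trigonometric components.
#'
#' @param x linear variable (e.g. position, cm).
#' @param theta angular variable in radians.
#' @param w nonnegative weights (posterior probabilities); `NULL` for the
#'   unweighted coefficient.
#' @return rcl in `[0, 1]`; NA when undefined (degenerate variance or
#'   `rCS^2 = 1`).
#' @export
circ_lin_corr <- function(x, theta, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  ok <- w > 0
  if (sum(ok) < 3) return(NA_real_)
  x <- x[ok]; theta <- theta[ok]; w <- w[ok]
  wc <- function(a, b) {
    am <- sum(w * a) / sum(w); bm <- sum(w * b) / sum(w)
    va <- sum(w * (a - am)^2); vb <- sum(w * (b - bm)^2)
    if (va <= 0 || vb <= 0) return(NA_real_)
    sum(w * (a - am) * (b - bm)) / sqrt(va * vb)
  }
  rXC <- wc(x, cos(theta)); rXS <- wc(x, sin(theta))
  rCS <- wc(cos(theta), sin(theta))
  if (anyNA(c(rXC, rXS, rCS)) || abs(rCS) >= 1 - 1e-12) return(NA_real_)
  num <- rXC^2 + rXS^2 - 2 * rXC * rXS * rCS
  sqrt(max(0, min(1, num / (1 - rCS^2))))
}

#' Per-window decoded posteriors in the travelling reference frame
#'
#' Decodes RUN spiking in 20 ms windows sliding by 5 ms inside epochs of
#' > 5 s constant running at >= 2.5 cm/s, using the epoch's direction map.
#' Each window's posterior is recentred so the rat's current position is at
#' 0 cm and the axis points along the direction of travel (CCW posteriors
#' are reversed), truncated to +/- `rel_pos_extent_cm`. Each window is
#' assigned its fraction of time elapsed through the current theta cycle by
#' linear interpolation between successive cycle boundaries.
#'
#' @param session immobility-filtered track RUN session.
#' @param geom [track_geometry()].
#' @param F_cw,F_ccw decoding matrices.
#' @param cell_ids ensemble cell order.
#' @param boundaries theta-cycle boundary times from [demarcate_theta()].
#' @param lin,runs precomputed linearization / directional epochs.
#' @param cfg [ps_config()].
#' @return list `rel_posteriors` (n_windows x n_rel_bins), `rel_pos`
#'   (bin centres, cm), `theta_frac`, `speed` per window.
#' @export
theta_sequence_windows <- function(session, geom, F_cw, F_ccw, cell_ids,
                                   boundaries, lin = NULL, runs = NULL,
                                   cfg = ps_config()) {
  pos <- session$position
  if (is.null(lin)) lin <- linearize(session, geom)
  if (is.null(runs)) runs <- split_directional_runs(lin, pos$t, geom$perimeter,
                                                    cfg$min_bout_s,
                                                    cfg$speed_floor)
  if (nrow(runs) == 0) return(NULL)
  sp <- attr(session, "speed")
  if (is.null(sp)) sp <- speed_estimate(session)
  bin_cm <- cfg$bin_cm
  nb <- round(geom$perimeter / bin_cm)
  K <- round(cfg$rel_pos_extent_cm / bin_cm)
  rel_pos <- seq(-K, K) * bin_cm
  rows <- list(); fr <- numeric(0); spd <- numeric(0)
  for (i in seq_len(nrow(runs))) {
    F <- if (runs$direction[i] == "CW") F_cw else F_ccw
    wc <- window_counts(session$spikes, cell_ids, runs$t_start[i],
                        runs$t_end[i], cfg$theta_window_s, cfg$theta_step_s)
    if (!length(wc$t_mid)) next
    post <- bayes_decode(wc$counts, F, cfg$theta_window_s)
    ## theta fraction of each window centre
    ci <- findInterval(wc$t_mid, boundaries)
    valid <- ci >= 1 & ci < length(boundaries)
    if (!any(valid)) next
    frac <- (wc$t_mid[valid] - boundaries[ci[valid]]) /
            (boundaries[ci[valid] + 1] - boundaries[ci[valid]])
    pi_ <- pmin(pmax(findInterval(wc$t_mid[valid], pos$t), 1L), nrow(pos))
    cur_bin <- (floor(lin[pi_] / bin_cm) %% nb) + 1L
    post <- post[valid, , drop = FALSE]
    m <- matrix(0, nrow(post), 2 * K + 1)
    for (r in seq_len(nrow(post))) {
      idx <- ((cur_bin[r] - 1 + seq(-K, K)) %% nb) + 1L
      v <- post[r, idx]
      if (runs$direction[i] == "CCW") v <- rev(v)
      m[r, ] <- v
    }
    rows[[length(rows) + 1]] <- m
    fr <- c(fr, frac)
    spd <- c(spd, sp[pi_])
  }
  if (!length(rows)) return(NULL)
  list(rel_posteriors = do.call(rbind, rows), rel_pos = rel_pos,
       theta_frac = fr, speed = spd)
}

#' Mean theta-sequence posterior and score for one session
#'
#' Windows are binned into 10 equal bins of elapsed theta-cycle time and
#' the posteriors averaged within each bin, yielding a (10 theta-time x
#' relative-position) matrix whose probability-weighted circular-linear
#' correlation is the theta sequence score.
#'
#' @param windows output of [theta_sequence_windows()] (possibly
#'   speed-subsampled).
#' @param n_bins number of theta-time bins.
#' @return list `posterior` (n_bins x n_rel_bins), `rel_pos`, `score`.
#' @export
theta_sequence_posterior <- function(windows, n_bins = 10) {
  if (is.null(windows)) return(NULL)
  b <- pmin(floor(windows$theta_frac * n_bins), n_bins - 1L) + 1L
  M <- matrix(NA_real_, n_bins, length(windows$rel_pos))
  for (k in seq_len(n_bins)) {
    sel <- b == k
    if (any(sel))
      M[k, ] <- colMeans(windows$rel_posteriors[sel, , drop = FALSE])
  }
  list(posterior = M, rel_pos = windows$rel_pos,
       score = theta_sequence_score(M, windows$rel_pos))
}

#' Theta sequence score of a mean posterior
#'
#' The probability-weighted circular-linear correlation between
#' relative position and theta-cycle angle; theta-time bin k maps to angle
#' `2*pi*(k - 0.5)/n_bins`.
#'
#' @param M n_theta_bins x n_rel_bins mean posterior.
#' @param rel_pos relative position bin centres (cm).
#' @export
theta_sequence_score <- function(M, rel_pos) {
  n_bins <- nrow(M)
  ang <- 2 * pi * (seq_len(n_bins) - 0.5) / n_bins
  ok <- !is.na(M[, 1])
  x <- rep(rel_pos, each = sum(ok))
  th <- rep(ang[ok], times = length(rel_pos))
  w <- as.vector(M[ok, , drop = FALSE])
  circ_lin_corr(x, th, w)
}

#' Subsample decode windows to a target median running speed
#'
#' Windows are sorted by speed and the fastest or slowest discarded one at
#' a time - whichever side moves the median toward the target - until the
#' median is as close to the target as discarding can make it (or one side
#' is exhausted). Used to compare sessions at a common 10.6 cm/s median.
#'
#' @param speeds window running speeds (cm/s).
#' @param target_median cm/s.
#' @return integer indices (into `speeds`) of the retained windows.
#' @export
speed_matched_subsample <- function(speeds, target_median = 10.6) {
  keep <- order(speeds)           # indices sorted by speed
  med <- stats::median(speeds[keep])
  repeat {
    if (length(keep) <= 2) break
    err <- abs(med - target_median)
    if (err == 0) break
    drop_hi <- med > target_median
    cand <- if (drop_hi) keep[-length(keep)] else keep[-1]
    new_med <- stats::median(speeds[cand])
    if (abs(new_med - target_median) >= err) break
    keep <- cand; med <- new_med
  }
  if (target_median < min(speeds) || target_median > max(speeds))
    warning("target median outside observed speed range; best achievable ",
            "median = ", signif(med, 4))
  sort(keep)
}

#' Main place field of a cell on the track
#'
#' Contiguous bins around the rate-map peak, extended circularly until the
#' rate falls below 20% of the peak or hits a local minimum below 50% of
#' the peak. Fields are found per direction and the direction whose main
#' field contains the most spikes is chosen.
#'
#' @param maps list with `CW` and `CCW` `ps_linear_ratemap`s for one cell
#'   (either may be `NULL`).
#' @param spike_bins optional list with per-direction in-epoch spike bin
#'   indices, used to pick the direction; omitted = direction with higher
#'   in-field smoothed spike mass.
#' @return list `direction`, `bins` (circular bin indices), `peak_bin`, or
#'   `NULL` when no field exists (flat or silent map).
#' @export
define_main_field <- function(maps, spike_bins = NULL) {
  fld <- function(m) {
    if (is.null(m)) return(NULL)
    r <- m$rates
    pk <- which.max(r)
    peak <- r[pk]
    if (peak <= 0 || diff(range(r)) < 1e-12) return(NULL)
    nb <- m$n_bins
    walk <- function(step) {
      out <- integer(0)
      j <- pk
      for (s in seq_len(nb - 1)) {
        nxt <- ((j - 1 + step) %% nb) + 1L
        if (r[nxt] < 0.20 * peak) break
        prv <- ((nxt - 1 + step) %% nb) + 1L  # bin beyond nxt
        if (r[nxt] < 0.50 * peak && r[nxt] <= r[j] && r[nxt] <= r[prv]) break
        out <- c(out, nxt)
        j <- nxt
        if (length(out) >= nb - 1) break
      }
      out
    }
    bins <- c(rev(walk(-1L)), pk, walk(1L))
    bins <- unique(bins)
    if (length(bins) >= nb) return(NULL)   # field spans whole track
    list(bins = bins, peak_bin = pk)
  }
  f_cw <- fld(maps$CW); f_ccw <- fld(maps$CCW)
  if (is.null(f_cw) && is.null(f_ccw)) return(NULL)
  mass <- function(f, m, sb) {
    if (is.null(f)) return(-Inf)
    if (!is.null(sb)) sum(sb %in% f$bins) else sum(m$spikes[f$bins])
  }
  m_cw <- mass(f_cw, maps$CW, spike_bins$CW)
  m_ccw <- mass(f_ccw, maps$CCW, spike_bins$CCW)
  if (m_cw >= m_ccw) c(f_cw, direction = "CW") else c(f_ccw, direction = "CCW")
}

#' Phase precession of one cell
#'
#' Circular-linear correlation between spike theta phase and the rat's
#' position through the cell's main field, pooled over all qualifying
#' passes (> 5 s constant running in the field's direction at
#' >= 2.5 cm/s). Cells are included only with spatial information > 0.15
#' and > 25 in-field spikes.
#'
#' @param cell_id the cell.
#' @param session immobility-filtered track RUN session.
#' @param geom [track_geometry()].
#' @param maps that cell's directional maps from [track_ratemaps()].
#' @param theta output of [demarcate_theta()] (per-sample phase).
#' @param lin,runs precomputed linearization / directional epochs.
#' @param cfg [ps_config()].
#' @return list `cell_id`, `included`, `rho`, `n_field_spikes`,
#'   `direction`, `field_bins`.
#' @export
phase_precession_score <- function(cell_id, session, geom, maps, theta,
                                   lin = NULL, runs = NULL,
                                   cfg = ps_config()) {
  pos <- session$position
  if (is.null(lin)) lin <- linearize(session, geom)
  if (is.null(runs)) runs <- split_directional_runs(lin, pos$t, geom$perimeter,
                                                    cfg$min_bout_s,
                                                    cfg$speed_floor)
  fail <- function() list(cell_id = cell_id, included = FALSE, rho = NA_real_,
                          n_field_spikes = 0L, direction = NA_character_,
                          field_bins = integer(0))
  field <- define_main_field(maps)
  if (is.null(field)) return(fail())
  dir <- field$direction
  m <- maps[[dir]]
  si <- spatial_information(m)
  if (is.na(si) || si <= cfg$min_spatial_information) return(fail())
  ep <- runs[runs$direction == dir, , drop = FALSE]
  sp <- session$spikes[session$spikes$cell_id == cell_id, , drop = FALSE]
  sp <- sp[in_epochs(sp$t, ep), , drop = FALSE]
  if (!nrow(sp)) return(fail())
  i <- pmin(pmax(findInterval(sp$t, pos$t), 1L), nrow(pos))
  sbin <- (floor(lin[i] / m$bin_cm) %% m$n_bins) + 1L
  infield <- sbin %in% field$bins
  nfs <- sum(infield)
  if (nfs <= cfg$min_field_spikes) return(fail())
  ## linear coordinate: distance into the field along travel direction
  entry <- field$bins[1]
  if (dir == "CCW") entry <- field$bins[length(field$bins)]
  d <- ((sbin[infield] - entry) %% m$n_bins) * m$bin_cm
  if (dir == "CCW") d <- ((entry - sbin[infield]) %% m$n_bins) * m$bin_cm
  fs <- session$lfp[[1]]$fs
  ph <- theta$phase_deg[pmin(pmax(round(sp$t[infield] * fs) + 1, 1),
                             length(theta$phase_deg))]
  rho <- circ_lin_corr(d, ph * pi / 180)
  list(cell_id = cell_id, included = TRUE, rho = rho,
       n_field_spikes = nfs, direction = dir, field_bins = field$bins)
}
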
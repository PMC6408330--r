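#' Ground truth for a synthetic session
#'
#' Defines the generative parameters every synthetic session is built from
#' and that downstream analyses must recover: Gaussian place fields tiling
#' the track, theta-modulated spiking with controllable phase precession
#' and theta-sequence compression, and rest events (replay lines,
#' stationary events, position-independent noise events).
#'
#' Defaults emulate a young-rat square-track session: 62.5 cm arms, 40
#' cells with evenly spaced field centres, 8 cm tuning width, 10 Hz peak
#' rate, 7 Hz theta.
#'
#' @param n_cells number of complex-spike cells.
#' @param side_cm track arm length (62.5 pup, 100 adult).
#' @param field_sigma_cm Gaussian tuning width.
#' @param peak_rate_hz in-field peak firing rate.
#' @param precession_slope_deg_cm phase advance per cm through the field
#'   (0 disables precession).
#' @param theta_compression dimensionless sweep multiplier: within each
#'   theta cycle the represented position sweeps from
#'   `-theta_compression * sweep_half_cm` behind to the same distance ahead
#'   of the rat (0 disables theta sequences).
#' @param sweep_half_cm half-extent of the full-compression sweep.
#' @param theta_hz LFP theta frequency (5-11 Hz across development).
#' @param theta_kappa von Mises concentration of the theta modulation of
#'   firing (0 = none; ~1.5 gives a realistic ~60 deg phase spread).
#' @param field_centers optional explicit centres (cm on the linearized
#'   track) for CW travel; default evenly spaced.
#' @param field_centers_ccw centres for CCW travel. Place fields remap
#'   between running directions, so the default decorrelates the two
#'   tilings deterministically (a coprime-stride permutation of the CW
#'   centres, shifted by half a spacing); pass `field_centers` to force
#'   direction-independent tuning.
#' @param replay_events data.frame `t_start`, `slope` (cm/s, signed:
#'   positive = CW travel), `duration` (s), `start_pos` (cm).
#' @param stationary_events data.frame `t_start`, `pos`, `duration`.
#' @param seed integer; fully determines the generated session.
#' @export
ground_truth <- function(n_cells = 40, side_cm = 62.5, field_sigma_cm = 8,
                         peak_rate_hz = 10, precession_slope_deg_cm = 0,
                         theta_compression = 0, sweep_half_cm = 20,
                         theta_hz = 7, theta_kappa = 1.5,
                         field_centers = NULL, field_centers_ccw = NULL,
                         replay_events = NULL, stationary_events = NULL,
                         seed = 1L) {
  perimeter <- 4 * side_cm
  if (is.null(field_centers))
    field_centers <- (seq_len(n_cells) - 0.5) * perimeter / n_cells
  stopifnot(all(field_centers >= 0 & field_centers < perimeter))
  if (is.null(field_centers_ccw)) {
    stride <- n_cells %/% 2 + 1L
    while (stride < n_cells && gcd2(stride, n_cells) != 1L)
      stride <- stride + 1L
    perm <- ((seq_len(n_cells) - 1L) * stride) %% n_cells + 1L
    field_centers_ccw <-
      (field_centers[perm] + perimeter / (2 * n_cells)) %% perimeter
  }
  if (!is.null(replay_events))
    stopifnot(all(abs(replay_events$slope) <= 2500))
  structure(list(n_cells = n_cells, side_cm = side_cm, perimeter = perimeter,
                 field_sigma_cm = field_sigma_cm,
                 peak_rate_hz = peak_rate_hz,
                 precession_slope_deg_cm = precession_slope_deg_cm,
                 theta_compression = theta_compression,
                 sweep_half_cm = sweep_half_cm, theta_hz = theta_hz,
                 theta_kappa = theta_kappa,
                 field_centers = field_centers,
                 field_centers_ccw = field_centers_ccw,
                 replay_events = replay_events,
                 stationary_events = stationary_events,
                 seed = as.integer(seed)),
            class = "ps_truth")
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

## circular Gaussian tuning curve of cell i evaluated at positions p
tuning_rate <- function(truth, i, p, direction = "CW") {
  ctr <- if (direction == "CW") truth$field_centers[i]
         else truth$field_centers_ccw[i]
  d <- circ_diff(p, ctr, truth$perimeter)
  truth$peak_rate_hz * exp(-d^2 / (2 * truth$field_sigma_cm^2))
}

## track-average rate of each cell (used for noise events)
mean_rates <- function(truth) {
  p <- seq(0, truth$perimeter, length.out = 512)
  vapply(seq_len(truth$n_cells),
         function(i) mean(tuning_rate(truth, i, p)), 0)
}

#' Idealized directional rate maps from ground truth
#'
#' The true tuning curves sampled at the analysis binning, wrapped as
#' `ps_linear_ratemap`s (uniform unit dwell; each direction uses its own
#' field centres). Used to decode against known maps, isolating decoder and
#' fitting behaviour from map-estimation noise.
#'
#' @param truth a [ground_truth()].
#' @param bin_cm analysis bin size.
#' @return list per cell of lists with `CW` and `CCW` maps.
#' @export
truth_linear_maps <- function(truth, bin_cm = 2.5) {
  nb <- round(truth$perimeter / bin_cm)
  ctr <- (seq_len(nb) - 0.5) * bin_cm
  lapply(seq_len(truth$n_cells), function(i) {
    one <- function(dir) {
      r <- tuning_rate(truth, i, ctr, dir)
      structure(list(direction = dir, rates = r, dwell = rep(1, nb),
                     spikes = r, dwell_smooth = rep(1, nb),
                     spikes_smooth = r, n_bins = nb, bin_cm = bin_cm,
                     perimeter = truth$perimeter),
                class = "ps_linear_ratemap")
    }
    list(CW = one("CW"), CCW = one("CCW"))
  })
}

#' Generate a square-track RUN session with known structure
#'
#' Behaviour alternates CW and CCW running bouts separated by pauses.
#' Spikes are drawn from an inhomogeneous Poisson process whose rate is a
#' circular Gaussian spatial tuning evaluated at the theta-swept
#' represented position, multiplied by a theta modulation whose preferred
#' phase advances with distance through the field at the precession slope.
#' The LFP contains theta at `truth$theta_hz`, delta, and white noise.
#'
#' @param truth a [ground_truth()].
#' @param duration session length (s); trials are 900 s, tests use less.
#' @param run_speed running speed during bouts (cm/s).
#' @param bout_s,pause_s bout and pause lengths (s).
#' @param fs_pos position sample rate (Hz); head-tracking default 50.
#' @param fs_lfp LFP sample rate (Hz).
#' @param randomize_phase_offsets if TRUE each cell gets a random preferred
#'   theta phase at field entry (used to decouple population sequences from
#'   single-cell precession); default all cells enter their field at
#'   0 deg (= the theta peak).
#' @return list `session` (a `ps_session`) and `truth`.
#' @export
generate_track_run <- function(truth, duration = 300, run_speed = 15,
                               bout_s = 20, pause_s = 3, fs_pos = 50,
                               fs_lfp = 1000, randomize_phase_offsets = FALSE) {
  set.seed(truth$seed)
  stopifnot(run_speed > 2.5, bout_s > 5)
  P <- truth$perimeter
  ## velocity profile on the 1 ms simulation grid
  dt <- 0.001
  n <- round(duration / dt)
  tgrid <- (seq_len(n) - 1) * dt
  cyc <- bout_s + pause_s
  phase_in_cycle <- tgrid %% cyc
  moving <- phase_in_cycle < bout_s
  dir <- ifelse((tgrid %/% cyc) %% 2 == 0, 1, -1)     # +1 CW, -1 CCW
  v <- ifelse(moving, dir * run_speed, 0)
  lin <- (cumsum(v) * dt) %% P
  ## LFP: theta + delta + noise
  nl <- round(duration * fs_lfp)
  tl <- (seq_len(nl) - 1) / fs_lfp
  theta_phase_l <- 2 * pi * truth$theta_hz * tl
  lfp <- cos(theta_phase_l) + 0.3 * cos(2 * pi * 2.5 * tl + 1) +
         0.2 * stats::rnorm(nl)
  ## spiking on the simulation grid
  theta_phase <- (2 * pi * truth$theta_hz * tgrid) %% (2 * pi)
  slope_rad <- truth$precession_slope_deg_cm * pi / 180
  span <- 2.5 * truth$field_sigma_cm
  ## sweep is anchored to the phase of maximal ensemble firing (the common
  ## field-entry phase advanced by the precession across half the field):
  ## its wrap then coincides with the demarcated cycle boundaries, giving a
  ## continuous behind-to-ahead sweep within each analysed cycle
  phi_c <- -slope_rad * span
  off_frac <- circ_diff_rad(theta_phase, phi_c) / (2 * pi)   # (-0.5, 0.5]
  sweep <- truth$theta_compression * truth$sweep_half_cm * 2 * off_frac
  rep_pos <- (lin + dir * sweep) %% P
  ## preferred phase at field entry; 0 (=360 deg) makes the precession
  ## sawtooth span one full cycle so the population sweep is continuous
  psi0 <- if (randomize_phase_offsets)
    stats::runif(truth$n_cells, 0, 2 * pi) else rep(0, truth$n_cells)
  spikes <- list()
  for (i in seq_len(truth$n_cells)) {
    ctr_t <- ifelse(dir > 0, truth$field_centers[i],
                    truth$field_centers_ccw[i])
    dd <- circ_diff(rep_pos, ctr_t, P)
    lam <- truth$peak_rate_hz * exp(-dd^2 / (2 * truth$field_sigma_cm^2))
    ## distance into the field along travel direction, 0 at the field edge
    d_in <- dir * circ_diff(lin, ctr_t, P) + span
    d_in <- pmin(pmax(d_in, 0), 2 * span)
    psi <- psi0[i] - slope_rad * d_in
    ## von Mises theta modulation with unit temporal mean
    k <- truth$theta_kappa
    mod <- if (k > 0) exp(k * cos(theta_phase - psi)) / besselI(k, 0)
           else rep(1, n)
    lam <- ifelse(moving, lam * mod, 0.1)
    k <- stats::rpois(n, lam * dt)
    st <- rep(tgrid[k > 0] + dt / 2, k[k > 0])
    if (length(st))
      spikes[[length(spikes) + 1]] <- data.frame(cell_id = i, t = st)
  }
  spikes <- if (length(spikes)) do.call(rbind, spikes)
            else data.frame(cell_id = integer(), t = numeric())
  spikes <- spikes[order(spikes$t), ]
  if (!any(moving)) stop("behaviour never exceeds the speed floor")
  ## position samples at fs_pos
  ip <- seq(1, n, by = round(1 / (fs_pos * dt)))
  xy <- track_point(track_geometry(side_cm = truth$side_cm), lin[ip])
  session <- ps_session("RUN_track",
                        spikes = spikes,
                        position = data.frame(t = tgrid[ip], x = xy[, 1],
                                              y = xy[, 2]),
                        lfp = list(list(samples = lfp, fs = fs_lfp)),
                        duration = duration,
                        track = track_geometry(side_cm = truth$side_cm))
  list(session = session, truth = truth)
}

#' Generate a rest session with embedded events
#'
#' The animal is immobile; the LFP carries delta, noise, and a
#' Gaussian-windowed 150 Hz ripple burst at every event. Replay events
#' emit spikes from cells in field-centre order along the line
#' `pos = start_pos + slope * (t - t_start)` (positional jitter =
#' `replay_sigma_cm`); stationary events make cells with centres within
#' `stationary_window_cm` of the event position co-fire; noise events emit
#' position-independent Poisson spikes at `noise_gain` x each cell's
#' track-average rate.
#'
#' @param truth a [ground_truth()] whose `replay_events` /
#'   `stationary_events` are laid into the session.
#' @param duration session length (s).
#' @param n_noise_events number of position-independent events appended at
#'   random non-overlapping times.
#' @param noise_event_s duration of each noise event.
#' @param noise_gain rate multiplier for noise-event spiking.
#' @param replay_peak_hz per-cell peak rate while the replay line crosses
#'   the field.
#' @param replay_sigma_cm positional jitter of replay spiking.
#' @param stationary_window_cm half-window of field centres recruited by a
#'   stationary event; `stationary_rate_hz` their event rate.
#' @param background_hz per-cell rest background rate.
#' @param fs_lfp LFP sample rate.
#' @return list `session`, `truth`, `events` (data.frame `t_start`,
#'   `t_end`, `kind`).
#' @export
generate_rest <- function(truth, duration = 120, n_noise_events = 0,
                          noise_event_s = 0.25, noise_gain = 5,
                          replay_peak_hz = 120, replay_sigma_cm = 5,
                          stationary_window_cm = 10, stationary_rate_hz = 40,
                          background_hz = 0.2, fs_lfp = 1000) {
  set.seed(truth$seed + 1L)
  P <- truth$perimeter
  ev <- data.frame(t_start = numeric(), t_end = numeric(), kind = character())
  if (!is.null(truth$replay_events)) {
    re <- truth$replay_events
    ev <- rbind(ev, data.frame(t_start = re$t_start,
                               t_end = re$t_start + re$duration,
                               kind = "replay"))
  }
  if (!is.null(truth$stationary_events)) {
    se <- truth$stationary_events
    ev <- rbind(ev, data.frame(t_start = se$t_start,
                               t_end = se$t_start + se$duration,
                               kind = "stationary"))
  }
  if (n_noise_events > 0) {
    slots <- noise_event_times(n_noise_events, duration, noise_event_s, ev)
    ev <- rbind(ev, data.frame(t_start = slots,
                               t_end = slots + noise_event_s,
                               kind = "noise"))
  }
  if (nrow(ev) && max(ev$t_end) > duration)
    stop("event extends beyond session end")
  ev <- ev[order(ev$t_start), ]
  rownames(ev) <- NULL
  ## LFP: delta + noise + ripple burst per event
  nl <- round(duration * fs_lfp)
  tl <- (seq_len(nl) - 1) / fs_lfp
  lfp <- 0.5 * cos(2 * pi * 2.5 * tl) + 0.15 * stats::rnorm(nl)
  for (i in seq_len(nrow(ev))) {
    tc <- (ev$t_start[i] + ev$t_end[i]) / 2
    win <- exp(-(tl - tc)^2 / (2 * 0.02^2))
    lfp <- lfp + 1.5 * win * sin(2 * pi * 150 * (tl - tc))
  }
  ## spikes: background + per-event structured rates on a 1 ms grid
  dt <- 0.001
  n <- round(duration / dt)
  tgrid <- (seq_len(n) - 1) * dt
  mr <- mean_rates(truth)
  spikes <- list()
  for (i in seq_len(truth$n_cells)) {
    lam <- rep(background_hz, n)
    for (j in seq_len(nrow(ev))) {
      sel <- tgrid >= ev$t_start[j] & tgrid < ev$t_end[j]
      if (ev$kind[j] == "noise") {
        lam[sel] <- lam[sel] + noise_gain * mr[i]
      } else if (ev$kind[j] == "stationary") {
        se <- truth$stationary_events
        row <- which(se$t_start == ev$t_start[j])[1]
        if (abs(circ_diff(truth$field_centers[i], se$pos[row], P)) <
            stationary_window_cm)
          lam[sel] <- lam[sel] + stationary_rate_hz
      } else {
        re <- truth$replay_events
        row <- which(re$t_start == ev$t_start[j])[1]
        pline <- (re$start_pos[row] +
                  re$slope[row] * (tgrid[sel] - re$t_start[row])) %% P
        ctr <- if (re$slope[row] >= 0) truth$field_centers[i]
               else truth$field_centers_ccw[i]
        d <- circ_diff(pline, ctr, P)
        lam[sel] <- lam[sel] +
          replay_peak_hz * exp(-d^2 / (2 * replay_sigma_cm^2))
      }
    }
    k <- stats::rpois(n, lam * dt)
    st <- rep(tgrid[k > 0] + dt / 2, k[k > 0])
    if (length(st))
      spikes[[length(spikes) + 1]] <- data.frame(cell_id = i, t = st)
  }
  spikes <- if (length(spikes)) do.call(rbind, spikes)
            else data.frame(cell_id = integer(), t = numeric())
  spikes <- spikes[order(spikes$t), ]
  ## immobile position trace (sub-mm jitter)
  tp <- seq(0, duration - 1 / 50, by = 1 / 50)
  pos <- data.frame(t = tp, x = 15 + stats::rnorm(length(tp), 0, 0.02),
                    y = 15 + stats::rnorm(length(tp), 0, 0.02))
  session <- ps_session("POST_rest", spikes = spikes, position = pos,
                        lfp = list(list(samples = lfp, fs = fs_lfp)),
                        duration = duration,
                        track = track_geometry(side_cm = truth$side_cm))
  list(session = session, truth = truth, events = ev)
}

## draw non-overlapping event start times avoiding existing events
noise_event_times <- function(n_events, duration, event_s, existing) {
  gap <- 0.15
  starts <- numeric(0)
  busy <- existing[, c("t_start", "t_end"), drop = FALSE]
  tries <- 0
  while (length(starts) < n_events) {
    tries <- tries + 1
    if (tries > 50000) stop("cannot place noise events without overlap")
    s <- stats::runif(1, 1, duration - event_s - 1)
    if (!nrow(busy) ||
        all(s + event_s + gap < busy$t_start | s > busy$t_end + gap)) {
      starts <- c(starts, s)
      busy <- rbind(busy, data.frame(t_start = s, t_end = s + event_s))
    }
  }
  sort(starts)
}

#' Position-independent candidate events for null calibration
#'
#' Generates `n_events` candidate-event spike rasters whose spikes are
#' homogeneous Poisson per cell (independent of position), together with
#' the idealized decoding maps, for calibrating the shuffle significance
#' test: because the spikes carry no spatial information, the real
#' map-assignment is exchangeable with any cell-identity shuffle and the
#' pipeline should pass ~5% of events.
#'
#' @param truth a [ground_truth()].
#' @param n_events number of events.
#' @param event_s event duration (s).
#' @param rate_gain multiplier on each cell's track-average rate.
#' @return list `events` (data.frame), `spikes` (data.frame over a
#'   concatenated timeline), `maps` ([truth_linear_maps()] output).
#' @export
generate_null_events <- function(truth, n_events = 200, event_s = 0.3,
                                 rate_gain = 5) {
  set.seed(truth$seed + 2L)
  mr <- mean_rates(truth) * rate_gain
  gap <- 0.2
  t0 <- (seq_len(n_events) - 1) * (event_s + gap)
  spikes <- list()
  for (e in seq_len(n_events)) for (i in seq_len(truth$n_cells)) {
    k <- stats::rpois(1, mr[i] * event_s)
    if (k > 0)
      spikes[[length(spikes) + 1]] <-
        data.frame(cell_id = i, t = t0[e] + sort(stats::runif(k, 0, event_s)))
  }
  spikes <- do.call(rbind, spikes)
  spikes <- spikes[order(spikes$t), ]
  list(events = data.frame(t_start = t0, t_end = t0 + event_s),
       spikes = spikes, maps = truth_linear_maps(truth))
}
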
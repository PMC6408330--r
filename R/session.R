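#' Construct a recording session
#'
#' A session bundles the spikes, tracked position, LFP and metadata of one
#' trial. Trials are either awake exploration (`RUN_openfield`, `RUN_track`)
#' or rest in a holding box (`PRE_rest`, `POST_rest`). All times are seconds
#' from session start, positions are cm.
#'
#' @param trial_kind one of `"RUN_openfield"`, `"RUN_track"`, `"PRE_rest"`,
#'   `"POST_rest"`.
#' @param spikes data.frame with integer `cell_id` and numeric `t` (s).
#' @param position data.frame with `t`, `x`, `y`; samples at a fixed rate.
#' @param lfp list of LFP channels, each `list(samples = <numeric volts>,
#'   fs = <Hz>)`.
#' @param duration session length in s (trials are 15 min by default).
#' @param track [track_geometry()] or `NULL` for open field / rest.
#' @param age_days animal age, metadata only.
#' @return an object of class `"ps_session"`.
#' @export
ps_session <- function(trial_kind, spikes, position, lfp = list(),
                       duration = 900, track = NULL, age_days = NA_integer_) {
  trial_kind <- match.arg(trial_kind,
    c("RUN_openfield", "RUN_track", "PRE_rest", "POST_rest"))
  spikes <- as.data.frame(spikes)
  position <- as.data.frame(position)
  stopifnot(all(c("cell_id", "t") %in% names(spikes)),
            all(c("t", "x", "y") %in% names(position)))
  if (nrow(spikes) && (min(spikes$t) < 0 || max(spikes$t) > duration))
    stop("spike times outside [0, duration]")
  if (nrow(position)) {
    if (min(position$t) < 0 || max(position$t) > duration)
      stop("position times outside [0, duration]")
    dt <- diff(position$t)
    if (any(dt <= 0))
      stop("non-monotonic position timestamps at index ",
           which(dt <= 0)[1] + 1L)
    if (length(dt) > 1 && diff(range(dt)) > 1e-6)
      stop("position sample rate is not constant")
  }
  spikes <- spikes[order(spikes$t), , drop = FALSE]
  rownames(spikes) <- NULL
  structure(list(trial_kind = trial_kind, spikes = spikes,
                 position = position, lfp = lfp, duration = duration,
                 track = track, age_days = age_days),
            class = "ps_session")
}

#' @export
print.ps_session <- function(x, ...) {
  cat(sprintf("<ps_session> %s: %.0f s, %d cells, %d spikes, %d LFP channel(s)\n",
              x$trial_kind, x$duration, n_cells(x), nrow(x$spikes),
              length(x$lfp)))
  invisible(x)
}

#' Number of distinct cells in a session
#' @param session a `ps_session`.
#' @export
n_cells <- function(session) length(unique(session$spikes$cell_id))

#' Square-track geometry
#'
#' The track runs along the walls of a square box (62.5 cm sides for pups,
#' 100 cm arms for adults). The linearized coordinate starts at the corner
#' nearest the origin and increases along the path
#' (0,0) -> (side,0) -> (side,side) -> (0,side) -> back, on the half-open
#' range `[0, perimeter)`; positive displacement along this path is labelled
#' CW. Linearization snaps positions, by angle about the track centroid, to
#' perimeter points spaced `step_cm` apart.
#'
#' @param side_cm arm length in cm.
#' @param width_cm track width in cm.
#' @param step_cm spacing of the linearization bin edges along the arms.
#' @export
track_geometry <- function(side_cm = 62.5, width_cm = 8.5, step_cm = 0.25) {
  stopifnot(side_cm > 0, step_cm > 0)
  structure(list(side_cm = side_cm, width_cm = width_cm, step_cm = step_cm,
                 perimeter = 4 * side_cm),
            class = "ps_track")
}

## (x, y) coordinates of the perimeter point at linear position s
track_point <- function(geom, s) {
  L <- geom$side_cm
  s <- s %% geom$perimeter
  arm <- floor(s / L)
  u <- s - arm * L
  x <- ifelse(arm == 0, u, ifelse(arm == 1, L, ifelse(arm == 2, L - u, 0)))
  y <- ifelse(arm == 0, 0, ifelse(arm == 1, u, ifelse(arm == 2, L, L - u)))
  cbind(x = x, y = y)
}

#' Map 2D track positions to the circular linearized coordinate
#'
#' Each sample is assigned, by its angle about the centroid of the four
#' corners, to the nearest of a set of perimeter points spaced
#' `geom$step_cm` apart. Output is in `[0, perimeter)`.
#'
#' @param session a track RUN `ps_session` (or a data.frame with x, y).
#' @param geom a [track_geometry()].
#' @return numeric vector of linear positions, one per position sample.
#' @export
linearize <- function(session, geom) {
  pos <- if (inherits(session, "ps_session")) session$position else session
  cx <- geom$side_cm / 2
  cy <- geom$side_cm / 2
  margin <- geom$width_cm
  out <- pmin(pmax(pos$x, -margin), geom$side_cm + margin)
  if (any(out != pos$x) || any(pos$y < -margin | pos$y > geom$side_cm + margin))
    warning("positions outside track bounding box clamped")
  s_grid <- seq(0, geom$perimeter - geom$step_cm, by = geom$step_cm)
  xy <- track_point(geom, s_grid)
  ang_grid <- atan2(xy[, 2] - cy, xy[, 1] - cx)
  ang <- atan2(pmin(pmax(pos$y, -margin), geom$side_cm + margin) - cy,
               pmin(pmax(pos$x, -margin), geom$side_cm + margin) - cx)
  ## nearest perimeter point by circular angular distance
  ord <- order(ang_grid)
  ga <- ang_grid[ord]
  idx <- findInterval(ang, ga)
  lo <- ifelse(idx == 0, length(ga), idx)
  hi <- ifelse(idx == length(ga), 1L, idx + 1L)
  d_lo <- abs(circ_diff_rad(ang, ga[lo]))
  d_hi <- abs(circ_diff_rad(ang, ga[hi]))
  pick <- ifelse(d_lo <= d_hi, lo, hi)
  s_grid[ord][pick]
}

## signed circular difference in radians, result in (-pi, pi]
circ_diff_rad <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Signed circular difference of linear positions
#'
#' @param a,b linear positions in cm.
#' @param perimeter track perimeter in cm.
#' @return difference wrapped to `(-perimeter/2, perimeter/2]`.
#' @export
circ_diff <- function(a, b, perimeter) {
  d <- (a - b) %% perimeter
  ifelse(d > perimeter / 2, d - perimeter, d)
}

#' Running speed from tracked position
#'
#' Positions are smoothed with a 400 ms boxcar (LED tracking noise), then
#' speed is the centered finite difference of the smoothed trajectory.
#'
#' @param session a `ps_session` with position samples.
#' @param smooth_s boxcar width in s.
#' @return numeric vector of speeds (cm/s), one per position sample.
#' @export
speed_estimate <- function(session, smooth_s = 0.4) {
  pos <- session$position
  n <- nrow(pos)
  if (n < 3) return(rep(0, n))
  dt <- pos$t[2] - pos$t[1]
  k <- max(1L, round(smooth_s / dt))
  xs <- boxcar(pos$x, k)
  ys <- boxcar(pos$y, k)
  vx <- c(xs[2] - xs[1], (xs[-(1:2)] - xs[1:(n - 2)]) / 2, xs[n] - xs[n - 1]) / dt
  vy <- c(ys[2] - ys[1], (ys[-(1:2)] - ys[1:(n - 2)]) / 2, ys[n] - ys[n - 1]) / dt
  sqrt(vx^2 + vy^2)
}

## boxcar smoothing with reflected edges
boxcar <- function(x, k) {
  if (k <= 1) return(x)
  pad <- (k %/% 2)
  xe <- c(rev(x[seq_len(pad)]), x, rev(x[(length(x) - pad + 1):length(x)]))
  f <- stats::filter(xe, rep(1 / k, k), sides = 2)
  as.numeric(f[(pad + 1):(pad + length(x))])
}

#' Remove periods of immobility
#'
#' Samples with speed below `speed_floor` (strictly `< floor` is excluded;
#' a sample at exactly the floor is retained) are dropped together with the
#' spikes that fall into the excluded epochs. The retained movement epochs
#' are attached as `attr(, "epochs")` (data.frame `t_start`, `t_end`) for
#' event analyses.
#'
#' @param session a `ps_session` with position.
#' @param speed_floor cm/s; the protocol's immobility criterion is 2.5 cm/s.
#' @return a filtered `ps_session`; if no sample moves, the result has zero
#'   position samples and is flagged with `attr(, "empty") = TRUE`.
#' @export
filter_immobility <- function(session, speed_floor = 2.5) {
  ## an already-filtered session carries the speeds of its retained samples;
  ## reusing them makes the filter idempotent (re-estimating across the
  ## excision gaps would nibble at epoch edges)
  sp <- attr(session, "speed")
  if (is.null(sp) || length(sp) != nrow(session$position))
    sp <- speed_estimate(session)
  keep <- sp >= speed_floor
  ep <- runs_to_epochs(keep, session$position$t)
  spikes <- session$spikes[in_epochs(session$spikes$t, ep), , drop = FALSE]
  rownames(spikes) <- NULL
  out <- session
  out$spikes <- spikes
  out$position <- session$position[keep, , drop = FALSE]
  rownames(out$position) <- NULL
  attr(out, "epochs") <- ep
  attr(out, "speed") <- sp[keep]
  if (!any(keep)) attr(out, "empty") <- TRUE
  out
}

## convert a logical run-length mask over samples into epochs
runs_to_epochs <- function(keep, t) {
  if (!any(keep)) return(data.frame(t_start = numeric(), t_end = numeric()))
  r <- rle(keep)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  i <- which(r$values)
  dt <- if (length(t) > 1) t[2] - t[1] else 0
  data.frame(t_start = t[starts[i]], t_end = t[ends[i]] + dt / 2)
}

## membership of times in a set of [t_start, t_end) epochs
in_epochs <- function(times, epochs) {
  if (nrow(epochs) == 0 || length(times) == 0)
    return(rep(FALSE, length(times)))
  idx <- findInterval(times, epochs$t_start)
  idx > 0 & times < epochs$t_end[pmax(idx, 1L)]
}
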
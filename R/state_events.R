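## --- spectral helpers -----------------------------------------------------

## DPSS (Slepian) tapers via the symmetric tridiagonal formulation.
## Cached per (n, nw, k) because the eigendecomposition is the costly part.
.taper_cache <- new.env(parent = emptyenv())

dpss_tapers <- function(n, nw = 2.5, k = max(1L, floor(2 * nw) - 1L)) {
  key <- sprintf("%d_%g_%d", n, nw, k)
  if (!is.null(.taper_cache[[key]])) return(.taper_cache[[key]])
  w <- nw / n
  tt <- seq_len(n) - 1
  diag_v <- ((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * w)
  off <- tt[-1] * (n - tt[-1]) / 2
  A <- matrix(0, n, n)
  diag(A) <- diag_v
  A[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  A[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  e <- eigen(A, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  ## standard polarity: each taper's mean (odd ones: leading lobe) positive
  for (j in seq_len(k)) {
    s <- sum(V[, j])
    if (abs(s) < 1e-8) s <- V[2, j] - V[1, j]
    if (s < 0) V[, j] <- -V[, j]
  }
  V <- sweep(V, 2, sqrt(colSums(V^2)), "/")
  .taper_cache[[key]] <- V
  V
}

## multitaper PSD of one (detrended) window; returns freq + power
multitaper_psd <- function(x, fs, nw = 2.5) {
  n <- length(x)
  x <- x - mean(x)
  V <- dpss_tapers(n, nw)
  P <- 0
  for (j in seq_len(ncol(V))) {
    X <- stats::fft(x * V[, j])
    P <- P + Mod(X)^2
  }
  P <- P / ncol(V) / fs
  nf <- floor(n / 2) + 1
  list(freq = (seq_len(nf) - 1) * fs / n, power = P[seq_len(nf)])
}

#' Peak frequency of the LFP spectrum within a band
#'
#' Argmax of the whole-trial FFT power spectrum restricted to the band;
#' used to locate the session's theta (5-11 Hz) and delta (1.5-4 Hz) peaks,
#' which shift with age.
#'
#' @param lfp an LFP channel `list(samples, fs)`.
#' @param band numeric length-2 `c(lo, hi)` in Hz.
#' @return peak frequency in Hz.
#' @export
band_peak_frequency <- function(lfp, band) {
  fs <- lfp$fs
  stopifnot(band[2] <= fs / 2)
  x <- lfp$samples - mean(lfp$samples)
  n <- length(x)
  P <- Mod(stats::fft(x))^2
  f <- (seq_len(n) - 1) * fs / n
  i <- which(f >= band[1] & f <= band[2])
  p <- P[i]
  if (diff(range(p)) < 1e-12 * max(1, max(p))) {
    warning("flat spectrum in band; returning lower band edge")
    return(band[1])
  }
  f[i][which.max(p)]
}

#' Classify brain state in overlapping LFP windows
#'
#' Multitaper PSDs (NW = 2.5) are computed in 1.6 s windows overlapping by
#' 0.8 s. Theta and delta power are integrated around the session's peak
#' frequencies (theta peak +/- 1.5 Hz, delta peak +/- 1 Hz, clipped to the
#' 5-11 and 1.5-4 Hz bands). A window is `rest` when speed < 2.5 cm/s and
#' theta/delta < 2, `waking_movement` when the ratio > 2 and speed > 2.5,
#' otherwise `other`.
#'
#' @param lfp an LFP channel `list(samples, fs)`.
#' @param speed_t,speed times and values of the running-speed series.
#' @param cfg [ps_config()].
#' @return data.frame `t_start`, `t_end`, `state`, `theta_power`,
#'   `delta_power`, `ratio`, `mean_speed`.
#' @export
classify_states <- function(lfp, speed_t, speed, cfg = ps_config()) {
  fs <- lfp$fs
  wlen <- round(cfg$state_window_s * fs)
  step <- round(cfg$state_step_s * fs)
  n <- length(lfp$samples)
  if (n < wlen) stop("LFP shorter than one state window")
  f_theta <- band_peak_frequency(lfp, cfg$theta_band)
  f_delta <- band_peak_frequency(lfp, cfg$delta_band)
  th_lo <- max(cfg$theta_band[1], f_theta - 1.5)
  th_hi <- min(cfg$theta_band[2], f_theta + 1.5)
  de_lo <- max(cfg$delta_band[1], f_delta - 1)
  de_hi <- min(cfg$delta_band[2], f_delta + 1)
  starts <- seq(1, n - wlen + 1, by = step)
  out <- data.frame(t_start = (starts - 1) / fs)
  out$t_end <- out$t_start + cfg$state_window_s
  tp <- dp <- ms <- numeric(length(starts))
  for (i in seq_along(starts)) {
    seg <- lfp$samples[starts[i]:(starts[i] + wlen - 1)]
    psd <- multitaper_psd(seg, fs, cfg$state_nw)
    tp[i] <- sum(psd$power[psd$freq >= th_lo & psd$freq <= th_hi])
    dp[i] <- sum(psd$power[psd$freq >= de_lo & psd$freq <= de_hi])
    sel <- speed_t >= out$t_start[i] & speed_t < out$t_end[i]
    ms[i] <- if (any(sel)) mean(speed[sel]) else 0
  }
  ratio <- tp / pmax(dp, .Machine$double.eps)
  state <- rep("other", length(starts))
  state[ms < cfg$speed_floor & ratio < cfg$state_ratio] <- "rest"
  state[ms > cfg$speed_floor & ratio > cfg$state_ratio] <- "waking_movement"
  out$state <- state
  out$theta_power <- tp; out$delta_power <- dp
  out$ratio <- ratio; out$mean_speed <- ms
  out
}

## --- filtering / envelopes ------------------------------------------------

## zero-phase order-4 Butterworth band-pass
bandpass <- function(x, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

## analytic signal via FFT
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## rolling RMS over a k-sample centred window
rolling_rms <- function(x, k) {
  k <- max(1L, k)
  m <- boxcar(x^2, k)
  sqrt(pmax(m, 0))
}

#' Detect sharp-wave ripples
#'
#' Each channel is band-pass filtered 100-250 Hz; instantaneous power is
#' the RMS over 7 ms windows. The channel whose envelope has the highest SD
#' defines events: every suprathreshold local peak (threshold = 99th
#' percentile of that channel's envelope over the whole trial) opens a
#' 100 ms window about the peak; overlapping windows are merged keeping the
#' higher peak.
#'
#' @param lfp_channels list of `list(samples, fs)`.
#' @param cfg [ps_config()].
#' @return data.frame `t_peak`, `t_start`, `t_end`, `peak_power`.
#' @export
detect_swr <- function(lfp_channels, cfg = ps_config()) {
  stopifnot(length(lfp_channels) >= 1)
  fs <- lfp_channels[[1]]$fs
  stopifnot(fs >= 600)
  envs <- lapply(lfp_channels, function(ch)
    rolling_rms(bandpass(ch$samples, ch$fs, cfg$ripple_band),
                round(cfg$rms_window_s * ch$fs)))
  best <- which.max(vapply(envs, stats::sd, 0))
  env <- envs[[best]]
  thr <- stats::quantile(env, cfg$swr_percentile, names = FALSE)
  above <- env > thr
  if (!any(above))
    return(data.frame(t_peak = numeric(), t_start = numeric(),
                      t_end = numeric(), peak_power = numeric()))
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  i <- which(r$values)
  pk_idx <- vapply(i, function(j) {
    seg <- starts[j]:ends[j]
    seg[which.max(env[seg])]
  }, 0L)
  ev <- data.frame(t_peak = (pk_idx - 1) / fs,
                   peak_power = env[pk_idx])
  ev$t_start <- ev$t_peak - cfg$swr_window_s / 2
  ev$t_end <- ev$t_peak + cfg$swr_window_s / 2
  ev <- ev[order(ev$t_start), ]
  ## merge overlapping windows, keep higher peak
  merged <- ev[1, , drop = FALSE]
  if (nrow(ev) > 1) for (j in 2:nrow(ev)) {
    m <- nrow(merged)
    if (ev$t_start[j] <= merged$t_end[m]) {
      merged$t_end[m] <- max(merged$t_end[m], ev$t_end[j])
      if (ev$peak_power[j] > merged$peak_power[m]) {
        merged$peak_power[m] <- ev$peak_power[j]
        merged$t_peak[m] <- ev$t_peak[j]
      }
    } else merged <- rbind(merged, ev[j, ])
  }
  rownames(merged) <- NULL
  merged[, c("t_peak", "t_start", "t_end", "peak_power")]
}

#' Detect multi-unit activity bursts
#'
#' All spikes of the ensemble are binned at 1 ms, smoothed with a Gaussian
#' kernel (sd 10 ms), and events are excursions above mean + 3 SD of the
#' smoothed train lasting 100-750 ms (bounds at the threshold crossings).
#'
#' @param spikes data.frame `cell_id`, `t` of all complex-spike cells.
#' @param duration session length in s.
#' @param cfg [ps_config()].
#' @return data.frame `t_start`, `t_end`, `duration`.
#' @export
detect_mua <- function(spikes, duration, cfg = ps_config()) {
  nb <- ceiling(duration / cfg$mua_bin_s)
  bins <- pmin(pmax(floor(spikes$t / cfg$mua_bin_s), 0), nb - 1) + 1L
  counts <- tabulate(bins, nb)
  sig_bins <- cfg$mua_sigma_s / cfg$mua_bin_s
  h <- ceiling(3 * sig_bins)
  k <- stats::dnorm(seq(-h, h), sd = sig_bins)
  k <- k / sum(k)
  sm <- as.numeric(stats::filter(c(rep(0, h), counts, rep(0, h)), k, sides = 2))
  sm <- sm[(h + 1):(h + nb)]
  thr <- mean(sm) + cfg$mua_sd * stats::sd(sm)
  above <- sm > thr
  if (!any(above))
    return(data.frame(t_start = numeric(), t_end = numeric(),
                      duration = numeric()))
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  i <- which(r$values)
  ev <- data.frame(t_start = (starts[i] - 1) * cfg$mua_bin_s,
                   t_end = ends[i] * cfg$mua_bin_s)
  ev$duration <- ev$t_end - ev$t_start
  ev <- ev[ev$duration >= cfg$mua_duration_s[1] &
           ev$duration <= cfg$mua_duration_s[2], , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Keep only MUA bursts that overlap a sharp-wave ripple
#'
#' Partial overlap suffices; events become the candidate replay events.
#'
#' @param mua output of [detect_mua()].
#' @param swr output of [detect_swr()].
#' @return `mua` rows whose `[t_start, t_end]` intersects any SWR window,
#'   with a `swr_coincident` flag column (always TRUE in the result).
#' @export
joint_events <- function(mua, swr) {
  if (nrow(mua) == 0 || nrow(swr) == 0) {
    mua$swr_coincident <- logical(nrow(mua))
    return(mua[0, , drop = FALSE])
  }
  hit <- vapply(seq_len(nrow(mua)), function(i)
    any(mua$t_start[i] <= swr$t_end & mua$t_end[i] >= swr$t_start), TRUE)
  out <- mua[hit, , drop = FALSE]
  out$swr_coincident <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Theta phase and theta-cycle boundaries
#'
#' The LFP is band-pass filtered around the session theta peak (+/- 2 Hz)
#' and per-sample phase taken from the analytic signal (0 deg at the filtered
#' LFP peak). The preferred ensemble phase is the 5-deg phase bin with
#' maximal ensemble spiking within the supplied run epochs; cycle
#' boundaries are the crossings of (preferred + 180 deg) mod 360.
#'
#' @param lfp LFP channel `list(samples, fs)`.
#' @param spikes ensemble spikes data.frame (`cell_id`, `t`).
#' @param run_epochs data.frame `t_start`, `t_end` of movement epochs.
#' @param cfg [ps_config()].
#' @return list with `phase_t`, `phase_deg` (per LFP sample),
#'   `preferred_phase` (deg), and `boundaries` (s, within run epochs).
#' @export
demarcate_theta <- function(lfp, spikes, run_epochs, cfg = ps_config()) {
  fs <- lfp$fs
  f0 <- band_peak_frequency(lfp, cfg$theta_band)
  band <- c(max(1, f0 - 2), f0 + 2)
  xf <- bandpass(lfp$samples, fs, band)
  an <- analytic_signal(xf)
  phase <- (Arg(an) * 180 / pi) %% 360
  t <- (seq_along(phase) - 1) / fs
  keep <- in_epochs(spikes$t, run_epochs)
  st <- spikes$t[keep]
  if (length(st) == 0) stop("no spikes in run epochs; preferred phase undefined")
  sp_phase <- phase[pmin(pmax(round(st * fs) + 1, 1), length(phase))]
  hcount <- tabulate(floor(sp_phase / 5) + 1L, 72L)
  preferred <- (which.max(hcount) - 0.5) * 5
  bphase <- (preferred + 180) %% 360
  ## unwrap phase and find crossings of bphase + 360k inside run epochs
  dp <- circ_diff_rad(phase[-1] * pi / 180, phase[-length(phase)] * pi / 180)
  u <- cumsum(c(phase[1] * pi / 180, dp)) * 180 / pi
  boundaries <- numeric(0)
  for (i in seq_len(nrow(run_epochs))) {
    sel <- which(t >= run_epochs$t_start[i] & t < run_epochs$t_end[i])
    if (length(sel) < 2) next
    us <- u[sel]
    lev <- seq(ceiling((min(us) - bphase) / 360),
               floor((max(us) - bphase) / 360)) * 360 + bphase
    for (L in lev) {
      j <- which(us[-length(us)] < L & us[-1] >= L)
      if (length(j))
        boundaries <- c(boundaries,
                        t[sel[j]] + (L - us[j]) / (us[j + 1] - us[j]) / fs)
    }
  }
  list(phase_t = t, phase_deg = phase, preferred_phase = preferred,
       boundaries = sort(boundaries))
}
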
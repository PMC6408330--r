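#' Adaptive-smoothed open-field rate map
#'
#' Positions and spikes are binned into 2.5 x 2.5 cm bins. For each bin a
#' circle centred on the bin is expanded in radius r until
#' r >= alpha / (d * sqrt(s)), where d is the dwell time (s) and s the
#' spike count inside the circle; the bin's rate is then s/d. Bins whose
#' criterion is never met at the environment-diagonal cap (which requires
#' s >= 1) are rated 0 if they carry dwell, and flagged unvisited if not.
#'
#' @param session an immobility-filtered open-field RUN `ps_session`.
#' @param cell_id cell to map; `NULL` pools all spikes.
#' @param side_cm environment side length.
#' @param bin_cm bin size.
#' @param alpha adaptive-smoothing constant (dimensionless).
#' @return a `ps_ratemap`: list with `rates`, `dwell`, `spikes` matrices
#'   (rows = y bins, cols = x bins), `visited` mask and `bin_cm`.
#' @export
adaptive_ratemap <- function(session, cell_id = NULL, side_cm = 62.5,
                             bin_cm = 2.5, alpha = 200) {
  pos <- session$position
  if (nrow(pos) == 0) stop("no position samples (all immobile?)")
  dt <- pos$t[2] - pos$t[1]
  nb <- ceiling(side_cm / bin_cm)
  bx <- pmin(pmax(floor(pos$x / bin_cm), 0), nb - 1) + 1L
  by <- pmin(pmax(floor(pos$y / bin_cm), 0), nb - 1) + 1L
  dwell <- matrix(0, nb, nb)
  for (i in seq_along(bx)) dwell[by[i], bx[i]] <- dwell[by[i], bx[i]] + dt
  if (sum(dwell) == 0) stop("zero total dwell")
  sp <- session$spikes
  if (!is.null(cell_id)) sp <- sp[sp$cell_id == cell_id, , drop = FALSE]
  spk <- matrix(0, nb, nb)
  if (nrow(sp)) {
    i <- pmin(pmax(findInterval(sp$t, pos$t), 1L), nrow(pos))
    for (j in i) spk[by[j], bx[j]] <- spk[by[j], bx[j]] + 1
  }
  adaptive_smooth(dwell, spk, bin_cm, alpha)
}

## the adaptive expansion itself, on prebinned dwell/spike matrices
adaptive_smooth <- function(dwell, spk, bin_cm, alpha = 200) {
  nb <- nrow(dwell)
  ctr <- (seq_len(nb) - 0.5) * bin_cm
  rates <- matrix(NA_real_, nb, nb)
  visited <- dwell > 0
  r_cap <- sqrt(2) * nb * bin_cm
  for (iy in seq_len(nb)) for (ix in seq_len(nb)) {
    if (!visited[iy, ix]) next
    d2 <- outer((ctr - ctr[iy])^2, (ctr - ctr[ix])^2, `+`)
    dist <- sqrt(d2)
    ord <- order(dist)
    dd <- cumsum(dwell[ord])
    ss <- cumsum(spk[ord])
    rr <- dist[ord]
    ok <- ss >= 1 & dd > 0 & rr >= alpha / (dd * sqrt(pmax(ss, 1)))
    k <- which(ok)[1]
    if (is.na(k) || rr[k] > r_cap) {
      rates[iy, ix] <- 0       # silent at cap but dwell present
    } else {
      rates[iy, ix] <- ss[k] / dd[k]
    }
  }
  structure(list(rates = rates, dwell = dwell, spikes = spk,
                 visited = visited, bin_cm = bin_cm),
            class = "ps_ratemap")
}

#' Split a linearized trajectory into CW and CCW constant-running epochs
#'
#' Maximal epochs of single-signed circular displacement at speed >=
#' `speed_floor`, lasting at least `min_bout` s. Direction comes from the
#' sign of displacement along the linearized coordinate (positive = CW).
#'
#' @param lin linear positions (cm), one per position sample.
#' @param t sample times (s).
#' @param perimeter track perimeter (cm).
#' @param min_bout minimum epoch length (s).
#' @param speed_floor minimum running speed (cm/s).
#' @return data.frame `t_start`, `t_end`, `direction` ("CW"/"CCW").
#' @export
split_directional_runs <- function(lin, t, perimeter, min_bout = 5,
                                   speed_floor = 2.5) {
  n <- length(lin)
  if (n < 3) return(data.frame(t_start = numeric(), t_end = numeric(),
                               direction = character()))
  dt <- t[2] - t[1]
  u <- c(0, cumsum(circ_diff(lin[-1], lin[-n], perimeter)))  # unwrapped
  k <- max(1L, round(0.4 / dt))
  us <- boxcar(u, k)
  v <- c(us[2] - us[1], (us[-(1:2)] - us[1:(n - 2)]) / 2, us[n] - us[n - 1]) / dt
  lab <- ifelse(abs(v) < speed_floor, 0L, ifelse(v > 0, 1L, -1L))
  r <- rle(lab)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values != 0L & (t[ends] - t[starts] + dt) >= min_bout
  data.frame(t_start = t[starts[keep]],
             t_end = t[ends[keep]] + dt / 2,
             direction = ifelse(r$values[keep] > 0, "CW", "CCW"),
             stringsAsFactors = FALSE)
}

#' Directional linearized rate maps for one cell
#'
#' Per direction, dwell and spike counts are accumulated in 2.5 cm circular
#' bins over that direction's constant-running epochs, both maps are
#' smoothed with a wrapped Gaussian kernel (sd 5 cm, truncated at +/- 3 sd
#' and renormalized), and the rate map is smoothed spikes / smoothed dwell.
#'
#' @param session track RUN `ps_session` (immobility-filtered).
#' @param geom [track_geometry()].
#' @param cell_id cell to map.
#' @param lin,runs optional precomputed [linearize()] output and
#'   [split_directional_runs()] epochs (recomputed if missing).
#' @param bin_cm bin size; `sigma_cm` kernel sd.
#' @return named list with `CW` and `CCW` entries, each a
#'   `ps_linear_ratemap` (`rates`, `dwell`, `spikes`, `n_bins`, `bin_cm`,
#'   `perimeter`, `direction`) or `NULL` when that direction has no epochs.
#' @export
track_ratemaps <- function(session, geom, cell_id, lin = NULL, runs = NULL,
                           bin_cm = 2.5, sigma_cm = 5) {
  pos <- session$position
  if (is.null(lin)) lin <- linearize(session, geom)
  if (is.null(runs)) runs <- split_directional_runs(lin, pos$t, geom$perimeter)
  sp <- session$spikes[session$spikes$cell_id == cell_id, , drop = FALSE]
  out <- list(CW = NULL, CCW = NULL)
  for (dir in c("CW", "CCW")) {
    ep <- runs[runs$direction == dir, , drop = FALSE]
    if (nrow(ep) == 0) next
    out[[dir]] <- linear_ratemap(lin, pos$t, sp$t, ep, geom$perimeter,
                                 bin_cm, sigma_cm, dir)
  }
  out
}

## build one direction's smoothed linear map
linear_ratemap <- function(lin, t, spike_t, epochs, perimeter,
                           bin_cm = 2.5, sigma_cm = 5, direction = "CW") {
  nb <- round(perimeter / bin_cm)
  dt <- t[2] - t[1]
  keep <- in_epochs(t, epochs)
  bins <- (floor(lin[keep] / bin_cm) %% nb) + 1L
  dwell <- tabulate(bins, nb) * dt
  st <- spike_t[in_epochs(spike_t, epochs)]
  spk <- numeric(nb)
  if (length(st)) {
    i <- pmin(pmax(findInterval(st, t), 1L), length(t))
    sbin <- (floor(lin[i] / bin_cm) %% nb) + 1L
    spk <- tabulate(sbin, nb)
  }
  ds <- circular_smooth(dwell, sigma_cm / bin_cm)
  ss <- circular_smooth(spk, sigma_cm / bin_cm)
  rates <- ifelse(ds > 0, ss / ds, 0)
  structure(list(direction = direction, rates = rates, dwell = dwell,
                 spikes = spk, dwell_smooth = ds, spikes_smooth = ss,
                 n_bins = nb, bin_cm = bin_cm, perimeter = perimeter),
            class = "ps_linear_ratemap")
}

#' Wrapped Gaussian smoothing of a circular vector
#'
#' Kernel sd is in bins, truncated at +/- 3 sd and renormalized so that it
#' sums to 1 (total dwell and spikes are conserved).
#'
#' @param x numeric vector on a circular domain.
#' @param sigma_bins kernel sd in bins.
#' @export
circular_smooth <- function(x, sigma_bins) {
  if (sigma_bins <= 0) return(x)
  h <- ceiling(3 * sigma_bins)
  k <- exp(-(seq(-h, h))^2 / (2 * sigma_bins^2))
  k <- k / sum(k)
  n <- length(x)
  out <- numeric(n)
  for (j in seq(-h, h)) {
    idx <- ((seq_len(n) - 1 + j) %% n) + 1L
    out <- out + k[j + h + 1] * x[idx]
  }
  out
}

#' Place-field similarity between two rate maps
#'
#' Pearson correlation over spatially corresponding bins, using only bins
#' visited in both maps (for linear maps, all bins with positive dwell).
#'
#' @param mapA,mapB two `ps_ratemap`s or two `ps_linear_ratemap`s with the
#'   same binning.
#' @param min_bins minimum jointly visited bins.
#' @return Pearson r, or NA when undefined (zero variance, too few bins).
#' @export
place_field_similarity <- function(mapA, mapB, min_bins = 10) {
  if (inherits(mapA, "ps_linear_ratemap")) {
    ok <- mapA$dwell > 0 & mapB$dwell > 0
    a <- mapA$rates[ok]; b <- mapB$rates[ok]
  } else {
    ok <- mapA$visited & mapB$visited
    a <- mapA$rates[ok]; b <- mapB$rates[ok]
  }
  if (sum(ok) < min_bins) return(NA_real_)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Skaggs spatial information of a rate map
#'
#' `sum_i p_i (lambda_i / lambda_bar) log2(lambda_i / lambda_bar)` with
#' `p_i` the dwell probability of bin i and `lambda_bar = sum p_i lambda_i`.
#'
#' @param map a `ps_ratemap` or `ps_linear_ratemap`.
#' @return bits/spike; NA when the mean rate is 0.
#' @export
spatial_information <- function(map) {
  if (inherits(map, "ps_linear_ratemap")) {
    ok <- map$dwell > 0
    p <- map$dwell[ok] / sum(map$dwell[ok])
    lam <- map$rates[ok]
  } else {
    ok <- map$visited & !is.na(map$rates)
    p <- map$dwell[ok] / sum(map$dwell[ok])
    lam <- map$rates[ok]
  }
  lbar <- sum(p * lam)
  if (lbar == 0) return(NA_real_)
  i <- lam > 0
  sum(p[i] * (lam[i] / lbar) * log2(lam[i] / lbar))
}
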
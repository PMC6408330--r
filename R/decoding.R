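#' Stack a set of per-cell linear rate maps into a decoding matrix
#'
#' @param maps list of `ps_linear_ratemap`s (one direction), one per cell,
#'   in cell order.
#' @param rate_floor_hz floor applied inside the decoder so log rates are
#'   finite; the maps themselves are not altered elsewhere.
#' @return matrix n_bins x n_cells of firing rates (Hz).
#' @export
ratemap_matrix <- function(maps, rate_floor_hz = 0.01) {
  F <- vapply(maps, function(m) pmax(m$rates, rate_floor_hz),
              numeric(maps[[1]]$n_bins))
  F
}

#' Bayesian population decoding of position
#'
#' Poisson population decoder with a uniform prior:
#' `P(pos) ~ prod_i f_i(pos)^{n_i} * exp(-tau * sum_i f_i(pos))`,
#' computed in log space and normalized per time window.
#'
#' @param counts n_cells x n_windows matrix of spike counts.
#' @param F n_bins x n_cells rate matrix from [ratemap_matrix()].
#' @param tau decoding window length (s).
#' @return n_windows x n_bins posterior matrix; each row sums to 1.
#' @export
bayes_decode <- function(counts, F, tau) {
  counts <- as.matrix(counts)
  LP <- log(F) %*% counts - tau * rowSums(F)   # n_bins x n_windows
  m <- apply(LP, 2, max)
  P <- exp(sweep(LP, 2, m))
  t(sweep(P, 2, colSums(P), "/"))
}

#' Bin event spikes into overlapping decode windows
#'
#' @param spikes data.frame `cell_id`, `t` restricted to the event.
#' @param cell_ids ensemble cell ids defining count rows.
#' @param t_start,t_end event bounds (s).
#' @param window_s,step_s decode window length and step.
#' @return list with `counts` (n_cells x n_windows) and `t_mid` (window
#'   centre times, s).
#' @export
window_counts <- function(spikes, cell_ids, t_start, t_end,
                          window_s = 0.020, step_s = 0.010) {
  nw <- max(0L, floor((t_end - t_start - window_s) / step_s + 1e-9) + 1L)
  if (nw == 0L) return(list(counts = matrix(0, length(cell_ids), 0),
                            t_mid = numeric(0)))
  w0 <- t_start + (seq_len(nw) - 1) * step_s
  counts <- matrix(0L, length(cell_ids), nw)
  idx <- match(spikes$cell_id, cell_ids)
  for (k in which(!is.na(idx))) {
    w <- which(spikes$t[k] >= w0 & spikes$t[k] < w0 + window_s)
    counts[idx[k], w] <- counts[idx[k], w] + 1L
  }
  list(counts = counts, t_mid = w0 + window_s / 2)
}

#' Decode a candidate event against one direction's rate maps
#'
#' @inheritParams window_counts
#' @param F rate matrix from [ratemap_matrix()].
#' @param cfg [ps_config()]; uses the 20 ms / 10 ms replay windows.
#' @return list `posterior` (n_windows x n_bins), `t_mid`, `counts`.
#' @export
decode_event <- function(spikes, cell_ids, t_start, t_end, F,
                         cfg = ps_config()) {
  wc <- window_counts(spikes, cell_ids, t_start, t_end,
                      cfg$replay_window_s, cfg$replay_step_s)
  post <- bayes_decode(wc$counts, F, cfg$replay_window_s)
  list(posterior = post, t_mid = wc$t_mid, counts = wc$counts)
}

#' Median online decoding error during RUN
#'
#' Positions are decoded from RUN spiking in non-overlapping 300 ms windows
#' inside constant-direction running epochs, with the epoch's own direction
#' map; error is the circular distance between the posterior argmax and the
#' rat's mean position in the window. The session-level gate for replay
#' analysis requires a median error < 10 cm.
#'
#' @param session immobility-filtered track RUN `ps_session`.
#' @param geom [track_geometry()].
#' @param F_cw,F_ccw decoding matrices per direction.
#' @param cell_ids ensemble cell ids (rows of the decoding matrices).
#' @param lin,runs precomputed linearization and directional epochs.
#' @param cfg [ps_config()].
#' @return list `median_error` (cm), `n_windows`, `errors`.
#' @export
online_decode_error <- function(session, geom, F_cw, F_ccw, cell_ids,
                                lin = NULL, runs = NULL, cfg = ps_config()) {
  pos <- session$position
  if (is.null(lin)) lin <- linearize(session, geom)
  if (is.null(runs)) runs <- split_directional_runs(lin, pos$t, geom$perimeter,
                                                    cfg$min_bout_s,
                                                    cfg$speed_floor)
  if (length(cell_ids) == 0) stop("empty ensemble: online decoding gate fails")
  bin_cm <- cfg$bin_cm
  nbins <- round(geom$perimeter / bin_cm)
  centers <- (seq_len(nbins) - 0.5) * bin_cm
  errs <- numeric(0)
  for (i in seq_len(nrow(runs))) {
    F <- if (runs$direction[i] == "CW") F_cw else F_ccw
    w0 <- seq(runs$t_start[i], runs$t_end[i] - cfg$online_window_s,
              by = cfg$online_window_s)
    if (!length(w0)) next
    for (ws in w0) {
      sel <- session$spikes$t >= ws & session$spikes$t < ws + cfg$online_window_s
      cnt <- tabulate(match(session$spikes$cell_id[sel], cell_ids),
                      length(cell_ids))
      post <- bayes_decode(matrix(cnt, ncol = 1), F, cfg$online_window_s)
      psel <- pos$t >= ws & pos$t < ws + cfg$online_window_s
      if (!any(psel)) next
      true_pos <- circ_mean_pos(lin[psel], geom$perimeter)
      errs <- c(errs, abs(circ_diff(centers[which.max(post[1, ])], true_pos,
                                    geom$perimeter)))
    }
  }
  if (length(errs) < 10)
    warning("fewer than 10 valid online-decoding windows; gate unreliable")
  list(median_error = stats::median(errs), n_windows = length(errs),
       errors = errs)
}

## circular mean position on [0, perimeter)
circ_mean_pos <- function(x, perimeter) {
  a <- x / perimeter * 2 * pi
  (atan2(mean(sin(a)), mean(cos(a))) %% (2 * pi)) / (2 * pi) * perimeter
}
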
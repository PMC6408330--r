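#' Spike counts of every cell in every SWR window
#'
#' @param spikes session spikes (`cell_id`, `t`).
#' @param swr data.frame from [detect_swr()], optionally restricted to
#'   rest-state windows by the caller.
#' @param cell_ids cell order for the rows.
#' @return n_cells x n_events count matrix.
#' @export
swr_count_matrix <- function(spikes, swr, cell_ids) {
  M <- matrix(0L, length(cell_ids), nrow(swr))
  idx <- match(spikes$cell_id, cell_ids)
  for (k in which(!is.na(idx))) {
    e <- which(spikes$t[k] >= swr$t_start & spikes$t[k] < swr$t_end)
    M[idx[k], e] <- M[idx[k], e] + 1L
  }
  M
}

#' SWR spiking correlation of a cell pair
#'
#' Pearson correlation of the two cells' per-event spike-count vectors.
#'
#' @param counts_a,counts_b per-SWR spike counts of the two cells.
#' @param min_events minimum number of events required.
#' @return Pearson r; NA when either vector has zero variance or there are
#'   too few events.
#' @export
swr_pair_correlation <- function(counts_a, counts_b, min_events = 10) {
  if (length(counts_a) < min_events) return(NA_real_)
  if (stats::sd(counts_a) == 0 || stats::sd(counts_b) == 0) return(NA_real_)
  stats::cor(counts_a, counts_b)
}

#' Theta-cycle co-firing of a cell pair
#'
#' Spikes of each cell are binned into theta-cycle temporal bins (cycles
#' restricted to waking-movement epochs by the caller via `boundaries`);
#' returns the Pearson correlation of the two count vectors, the number of
#' cycles in which both fired, and the pair's total spikes in those cycles.
#'
#' @param spikes_a,spikes_b spike time vectors.
#' @param boundaries theta-cycle boundary times from [demarcate_theta()].
#' @return list `r`, `n_cofire_cycles`, `n_spikes_cofire_cycles`.
#' @export
theta_cofire_correlation <- function(spikes_a, spikes_b, boundaries) {
  nc <- length(boundaries) - 1
  if (nc < 2) return(list(r = NA_real_, n_cofire_cycles = 0L,
                          n_spikes_cofire_cycles = 0L))
  bin <- function(st) {
    i <- findInterval(st, boundaries)
    tabulate(i[i >= 1 & i <= nc], nc)
  }
  ca <- bin(spikes_a); cb <- bin(spikes_b)
  co <- ca > 0 & cb > 0
  r <- if (stats::sd(ca) == 0 || stats::sd(cb) == 0) NA_real_
       else stats::cor(ca, cb)
  list(r = r, n_cofire_cycles = sum(co),
       n_spikes_cofire_cycles = sum(ca[co]) + sum(cb[co]))
}

#' Build the cell-pair reactivation table for a PRE/RUN/POST triple
#'
#' One row per unordered pair of cells passing the RUN spike-count filter
#' (> `min_spikes_run` spikes after immobility filtering). Place-field
#' similarity comes from the RUN maps (adaptive open-field maps for an
#' open-field RUN, CW linear maps for a track RUN); SWR correlations from
#' the PRE and POST rest sessions; theta co-firing from RUN theta cycles
#' when `boundaries` is supplied. Plasticity is `swr_r_post - swr_r_pre`.
#'
#' @param pre,run,post `ps_session`s with the same cell ids.
#' @param run_maps named list of rate maps per cell id (each a `ps_ratemap`
#'   or a `CW`/`CCW` pair of `ps_linear_ratemap`s).
#' @param swr_pre,swr_post SWR tables (rest-restricted) for the two rest
#'   sessions.
#' @param boundaries optional RUN theta-cycle boundaries.
#' @param cfg [ps_config()].
#' @return data.frame with one row per pair: `cell_a`, `cell_b`, `pfs`,
#'   `swr_r_pre`, `swr_r_post`, `plasticity`, `theta_cofire_r`,
#'   `n_cofire_cycles`, `n_spikes_cofire_cycles`.
#' @export
build_pair_table <- function(pre, run, post, run_maps, swr_pre, swr_post,
                             boundaries = NULL, cfg = ps_config()) {
  counts <- table(run$spikes$cell_id)
  ids <- sort(as.integer(names(counts)[counts > cfg$min_spikes_run]))
  ids <- ids[vapply(ids, function(i) !is.null(run_maps[[as.character(i)]]),
                    TRUE)]
  present <- function(s) unique(s$spikes$cell_id)
  ids <- ids[ids %in% present(pre) & ids %in% present(post)]
  if (length(ids) < 2)
    return(data.frame(cell_a = integer(), cell_b = integer(),
                      pfs = numeric(), swr_r_pre = numeric(),
                      swr_r_post = numeric(), plasticity = numeric(),
                      theta_cofire_r = numeric(),
                      n_cofire_cycles = integer(),
                      n_spikes_cofire_cycles = integer()))
  Mpre <- swr_count_matrix(pre$spikes, swr_pre, ids)
  Mpost <- swr_count_matrix(post$spikes, swr_post, ids)
  pair_pfs <- function(a, b) {
    ma <- run_maps[[as.character(a)]]; mb <- run_maps[[as.character(b)]]
    if (inherits(ma, "ps_ratemap")) place_field_similarity(ma, mb)
    else if (!is.null(ma$CW) && !is.null(mb$CW))
      place_field_similarity(ma$CW, mb$CW)
    else NA_real_
  }
  rows <- list()
  for (ai in seq_along(ids)[-length(ids)]) for (bi in (ai + 1):length(ids)) {
    a <- ids[ai]; b <- ids[bi]
    rp <- swr_pair_correlation(Mpre[ai, ], Mpre[bi, ])
    ro <- swr_pair_correlation(Mpost[ai, ], Mpost[bi, ])
    th <- if (!is.null(boundaries))
      theta_cofire_correlation(run$spikes$t[run$spikes$cell_id == a],
                               run$spikes$t[run$spikes$cell_id == b],
                               boundaries)
    else list(r = NA_real_, n_cofire_cycles = NA_integer_,
              n_spikes_cofire_cycles = NA_integer_)
    rows[[length(rows) + 1]] <- data.frame(
      cell_a = a, cell_b = b, pfs = pair_pfs(a, b),
      swr_r_pre = rp, swr_r_post = ro, plasticity = ro - rp,
      theta_cofire_r = th$r, n_cofire_cycles = th$n_cofire_cycles,
      n_spikes_cofire_cycles = th$n_spikes_cofire_cycles)
  }
  do.call(rbind, rows)
}

#' Coupling between place-field similarity and SWR co-firing
#'
#' Pearson correlation across pairs between PFS (or any RUN co-firing
#' measure) and the PRE or POST SWR spiking correlation, with
#' `SE = sqrt((1 - r^2)/(n - 2))` and a two-sided p from `t = r/SE`.
#'
#' @param pairs table from [build_pair_table()].
#' @param which `"pre"` or `"post"`.
#' @param x column name of the RUN measure (default `"pfs"`).
#' @return list `r`, `se`, `p`, `n`; all NA when < 3 complete pairs.
#' @export
pfs_swr_coupling <- function(pairs, which = c("post", "pre"), x = "pfs") {
  which <- match.arg(which)
  y <- if (which == "post") pairs$swr_r_post else pairs$swr_r_pre
  xv <- pairs[[x]]
  ok <- !is.na(xv) & !is.na(y)
  n <- sum(ok)
  if (n < 3) return(list(r = NA_real_, se = NA_real_, p = NA_real_, n = n))
  r <- stats::cor(xv[ok], y[ok])
  se <- sqrt((1 - r^2) / (n - 2))
  t <- r / se
  list(r = r, se = se, p = 2 * stats::pt(-abs(t), df = n - 2), n = n)
}

#' Plasticity as a function of RUN co-activity
#'
#' Pairs are binned by a RUN co-firing measure; each bin's mean plasticity
#' (POST - PRE SWR correlation) is tested against zero with a one-sample
#' t-test. Reports the smallest bin with p < 0.05 and a positive mean.
#'
#' @param pairs table from [build_pair_table()].
#' @param x `"n_cofire_cycles"` or `"n_spikes_cofire_cycles"`.
#' @param edges bin edges (left-closed); default log-spaced.
#' @return list `table` (data.frame bin, lo, hi, n, mean, sem, p) and
#'   `smallest_significant_bin` (index into the table or NA).
#' @export
plasticity_curve <- function(pairs, x = "n_cofire_cycles",
                             edges = c(1, 2, 4, 8, 16, 32, 64, Inf)) {
  v <- pairs[[x]]
  pl <- pairs$plasticity
  ok <- !is.na(v) & !is.na(pl)
  v <- v[ok]; pl <- pl[ok]
  rows <- list()
  for (i in seq_len(length(edges) - 1)) {
    sel <- v >= edges[i] & v < edges[i + 1]
    n <- sum(sel)
    if (n < 2) next
    tt <- one_sample_t(pl[sel])
    rows[[length(rows) + 1]] <- data.frame(
      bin = i, lo = edges[i], hi = edges[i + 1], n = n,
      mean = mean(pl[sel]), sem = stats::sd(pl[sel]) / sqrt(n),
      p = tt$p)
  }
  tab <- if (length(rows)) do.call(rbind, rows)
         else data.frame(bin = integer(), lo = numeric(), hi = numeric(),
                         n = integer(), mean = numeric(), sem = numeric(),
                         p = numeric())
  hit <- which(!is.na(tab$p) & tab$p < 0.05 & tab$mean > 0)
  list(table = tab,
       smallest_significant_bin = if (length(hit)) tab$bin[hit[1]] else NA_integer_)
}
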
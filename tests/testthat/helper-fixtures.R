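# Shared fixtures. Expensive generated sessions are memoized per test run.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

prep_run <- function(tr, duration = 180) {
  gen <- generate_track_run(tr, duration = duration)
  g <- gen$session$track
  sf <- filter_immobility(gen$session)
  lin <- linearize(sf, g)
  runs <- split_directional_runs(lin, sf$position$t, g$perimeter)
  list(truth = tr, session = gen$session, filtered = sf, geom = g,
       lin = lin, runs = runs)
}

# a short track RUN with theta-sequence compression (no precession),
# used by the map/decoding/sequence tests
fix_run <- function() memo("run", {
  prep_run(ground_truth(n_cells = 30, seed = 101, theta_compression = 0.8))
})

fix_theta <- function() memo("theta", {
  f <- fix_run()
  demarcate_theta(f$session$lfp[[1]], f$filtered$spikes, f$runs)
})

# a RUN with single-cell phase precession (no compression sweep),
# used by the precession tests
fix_run_prec <- function() memo("run_prec", {
  prep_run(ground_truth(n_cells = 30, seed = 102,
                        precession_slope_deg_cm = 8, theta_kappa = 2))
})

fix_theta_prec <- function() memo("theta_prec", {
  f <- fix_run_prec()
  demarcate_theta(f$session$lfp[[1]], f$filtered$spikes, f$runs)
})

# synthetic trajectory helpers ------------------------------------------------

# position samples moving at a constant speed along the track
const_speed_position <- function(speed, duration, fs = 50, geom = NULL) {
  if (is.null(geom)) geom <- track_geometry(62.5)
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  s <- (speed * t) %% geom$perimeter
  xy <- placeseq:::track_point(geom, s)
  data.frame(t = t, x = xy[, 1], y = xy[, 2])
}

# delta-line posterior: all mass in the wrapped 25 cm band of a line
band_posterior <- function(slope, start, nt, nb, bin_cm = 2.5,
                           step_s = 0.01, band_cm = 25) {
  tm <- (seq_len(nt) - 1) * step_s
  ctr <- (seq_len(nb) - 0.5) * bin_cm
  P <- nb * bin_cm
  post <- matrix(0, nt, nb)
  for (t in seq_len(nt)) {
    p <- (start + slope * tm[t]) %% P
    inband <- abs(circ_diff(ctr, p, P)) <= band_cm / 2
    post[t, inband] <- 1 / sum(inband)
  }
  list(posterior = post, t_mid = tm)
}
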
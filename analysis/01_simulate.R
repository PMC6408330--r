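#!/usr/bin/env Rscript
# Simulate one synthetic experiment: a PRE rest session with unstructured
# population events, a square-track RUN session with place fields, theta
# modulation and phase precession, and a POST rest session with embedded
# replay trajectories and stationary reactivation events. Sessions are
# written in the package's on-disk format under results/sessions/.

suppressPackageStartupMessages(library(placeseq))

seed <- 20260928L
n_cells <- 35

truth <- ground_truth(
  n_cells = n_cells, side_cm = 62.5, field_sigma_cm = 8, peak_rate_hz = 10,
  precession_slope_deg_cm = 8, theta_kappa = 2, theta_hz = 7, seed = seed)

run <- generate_track_run(truth, duration = 300)

# POST: replay events spanning the slope grid plus stationary events
replay <- data.frame(
  t_start = seq(6, by = 9, length.out = 10),
  slope = c(250, -400, 600, 800, -1000, 1200, 500, -700, 900, 1500),
  duration = 0.35,
  start_pos = seq(5, 230, length.out = 10))
stationary <- data.frame(
  t_start = seq(100, by = 2.2, length.out = 8),
  pos = seq(15, 225, length.out = 8), duration = 0.15)
truth_post <- truth
truth_post$replay_events <- replay
truth_post$stationary_events <- stationary
post <- generate_rest(truth_post, duration = 120, replay_peak_hz = 150)

# PRE: position-independent noise events only
truth_pre <- truth
truth_pre$seed <- seed + 1L
pre <- generate_rest(truth_pre, duration = 120, n_noise_events = 25)
pre$session$trial_kind <- "PRE_rest"

dir.create("results/sessions", recursive = TRUE, showWarnings = FALSE)
write_session(run$session, "results/sessions/run")
write_session(pre$session, "results/sessions/pre")
write_session(post$session, "results/sessions/post")
utils::write.table(replay, "results/sessions/ground_truth_replay.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(
  data.frame(cell_id = seq_len(n_cells),
             center_cw = truth$field_centers,
             center_ccw = truth$field_centers_ccw),
  "results/sessions/ground_truth_fields.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("RUN: %d spikes from %d cells over %.0f s\n",
            nrow(run$session$spikes), n_cells, run$session$duration))
cat(sprintf("PRE: %d noise events; POST: %d replay + %d stationary events\n",
            25, nrow(replay), nrow(stationary)))
cat("sessions written under results/sessions/\n")
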
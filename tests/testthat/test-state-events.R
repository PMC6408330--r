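test_that("band peak frequency finds injected sinusoids", {
  fs <- 250
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  df <- 1 / 60
  set.seed(3)
  x <- sin(2 * pi * 6.5 * t) + 0.5 * sin(2 * pi * 3 * t) + 0.1 * rnorm(length(t))
  expect_lt(abs(band_peak_frequency(list(samples = x, fs = fs), c(5, 11)) - 6.5),
            2 * df + 1e-9)
  expect_lt(abs(band_peak_frequency(list(samples = x, fs = fs), c(1.5, 4)) - 3),
            2 * df + 1e-9)
  expect_warning(band_peak_frequency(list(samples = rep(0, fs * 10), fs = fs),
                                     c(5, 11)), "flat")
})

test_that("brain-state classification follows the power ratio and speed", {
  fs <- 200
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  set.seed(4)
  theta_lfp <- list(samples = sin(2 * pi * 7 * t) + 0.05 * rnorm(length(t)),
                    fs = fs)
  delta_lfp <- list(samples = sin(2 * pi * 2.5 * t) + 0.05 * rnorm(length(t)),
                    fs = fs)
  ts_ <- seq(0, 30, by = 0.02)
  st1 <- classify_states(theta_lfp, ts_, rep(10, length(ts_)))
  expect_true(all(st1$state == "waking_movement"))
  st2 <- classify_states(delta_lfp, ts_, rep(0, length(ts_)))
  expect_true(all(st2$state == "rest"))
  # high theta but no movement, or movement without theta, is "other"
  st3 <- classify_states(theta_lfp, ts_, rep(0, length(ts_)))
  expect_true(all(st3$state == "other"))
  st4 <- classify_states(delta_lfp, ts_, rep(10, length(ts_)))
  expect_true(all(st4$state == "other"))
  # windows are 1.6 s overlapping by 0.8 s
  expect_equal(unique(round(diff(st1$t_start), 6)), 0.8)
  expect_equal(unique(round(st1$t_end - st1$t_start, 6)), 1.6)
})

test_that("generated rest sessions classify overwhelmingly as rest", {
  tr <- ground_truth(n_cells = 10, seed = 21)
  r <- generate_rest(tr, duration = 40, n_noise_events = 3)
  st <- classify_states(r$session$lfp[[1]], r$session$position$t,
                        speed_estimate(r$session))
  expect_gte(mean(st$state == "rest"), 0.9)
})

test_that("the SWR threshold is the 99th envelope percentile", {
  set.seed(5)
  lfp <- list(samples = rnorm(60000), fs = 1000)
  env <- placeseq:::rolling_rms(placeseq:::bandpass(lfp$samples, 1000,
                                                    c(100, 250)), 7)
  thr <- quantile(env, 0.99, names = FALSE)
  expect_lt(abs(mean(env > thr) - 0.01), 0.001)
  expect_silent(detect_swr(list(lfp)))
})

test_that("injected ripples are detected and nearby windows merged", {
  fs <- 1000
  t <- seq(0, 30 - 1 / fs, by = 1 / fs)
  set.seed(6)
  base <- 0.3 * sin(2 * pi * 2.5 * t) + 0.05 * rnorm(length(t))
  ripple <- function(tc) 1.5 * exp(-(t - tc)^2 / (2 * 0.02^2)) *
    sin(2 * pi * 150 * (t - tc))
  # the percentile threshold always marks ~1% of samples, so noise peaks
  # are detected alongside the burst: the injected ripple must dominate
  ev <- detect_swr(list(list(samples = base + ripple(10), fs = fs)))
  top <- ev[which.max(ev$peak_power), ]
  expect_true(top$t_peak > 9.95 && top$t_peak < 10.05)
  # merged windows never overlap
  expect_true(all(ev$t_start[-1] >= ev$t_end[-nrow(ev)]))
  # two bursts 60 ms apart fall in overlapping 100 ms windows -> one event
  ev2 <- detect_swr(list(list(samples = base + ripple(10) + ripple(10.06),
                              fs = fs)))
  near2 <- ev2[ev2$t_end > 9.9 & ev2$t_start < 10.2, ]
  expect_equal(nrow(near2), 1)
  # well-separated bursts stay separate
  ev3 <- detect_swr(list(list(samples = base + ripple(10) + ripple(15),
                              fs = fs)))
  expect_equal(sum(abs(ev3$t_peak - 10) < 0.06), 1)
  expect_equal(sum(abs(ev3$t_peak - 15) < 0.06), 1)
})

test_that("MUA bursts respect the 100-750 ms duration bounds", {
  set.seed(7)
  # homogeneous ensemble background
  bg <- data.frame(cell_id = sample(1:20, 3000, TRUE),
                   t = sort(runif(3000, 0, 60)))
  ev0 <- detect_mua(bg, 60)
  if (nrow(ev0))
    expect_true(all(ev0$duration >= 0.1 & ev0$duration <= 0.75))
  burst <- function(tc, len, rate = 1500) {
    k <- rpois(1, rate * len)
    data.frame(cell_id = sample(1:20, k, TRUE), t = sort(runif(k, tc, tc + len)))
  }
  s1 <- rbind(bg, burst(30, 0.2))
  s1 <- s1[order(s1$t), ]
  ev1 <- detect_mua(s1, 60)
  hit <- ev1$t_start < 30.2 & ev1$t_end > 30
  expect_equal(sum(hit), 1)
  expect_true(all(ev1$duration >= 0.1 & ev1$duration <= 0.75))
  # a 900 ms burst is too long and must be rejected
  s2 <- rbind(bg, burst(30, 0.9))
  s2 <- s2[order(s2$t), ]
  ev2 <- detect_mua(s2, 60)
  expect_false(any(ev2$t_start < 30.9 & ev2$t_end > 30))
})

test_that("joint events require SWR overlap, even partial", {
  mua <- data.frame(t_start = c(1.00, 1.00), t_end = c(1.20, 1.20),
                    duration = 0.2)
  swr1 <- data.frame(t_peak = 1.24, t_start = 1.19, t_end = 1.29,
                     peak_power = 1)
  swr2 <- data.frame(t_peak = 1.30, t_start = 1.25, t_end = 1.35,
                     peak_power = 1)
  expect_equal(nrow(joint_events(mua[1, ], swr1)), 1)
  expect_equal(nrow(joint_events(mua[1, ], swr2)), 0)
})

test_that("embedded replay events survive the joint SWR/MUA filter", {
  re <- data.frame(t_start = seq(5, by = 8, length.out = 3),
                   slope = c(400, 600, 800), duration = 0.3,
                   start_pos = c(20, 120, 220))
  tr <- ground_truth(n_cells = 40, seed = 23, replay_events = re)
  r <- generate_rest(tr, duration = 30, replay_peak_hz = 200)
  ev <- joint_events(detect_mua(r$session$spikes, 30),
                     detect_swr(r$session$lfp))
  # every truth event is recovered by at least one candidate (sequential
  # burst profiles can fragment at the 3 SD crossings), and no candidate
  # falls outside a truth window
  hits <- vapply(seq_len(nrow(re)), function(i)
    sum(ev$t_start < re$t_start[i] + re$duration[i] &
        ev$t_end > re$t_start[i]), 0L)
  expect_true(all(hits >= 1))
  expect_equal(sum(hits), nrow(ev))
})

test_that("theta demarcation recovers phase structure", {
  fs <- 1000
  t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  lfp <- list(samples = cos(2 * pi * 8 * t), fs = fs)
  # spikes at the LFP peaks -> preferred phase ~0, boundaries at 180 deg
  spk <- data.frame(cell_id = 1L, t = seq(1, 19, by = 1 / 8))
  ep <- data.frame(t_start = 0.5, t_end = 19.5)
  th <- demarcate_theta(lfp, spk, ep)
  expect_lt(min(abs(c(th$preferred_phase, th$preferred_phase - 360))), 10)
  # pure sinusoid: every cycle lasts 1/8 s
  expect_lt(max(abs(diff(th$boundaries) - 1 / 8)), 0.002)
  # boundaries sit 180 degrees from the preferred phase
  i <- pmin(round(th$boundaries * fs) + 1, length(lfp$samples))
  ph <- th$phase_deg[i]
  d <- abs(circ_diff(ph, (th$preferred_phase + 180) %% 360, 360))
  expect_lt(max(d), 10)
  expect_error(demarcate_theta(lfp, spk[0, ], ep), "preferred phase")
})

test_that("theta boundaries partition run epochs without gaps", {
  f <- fix_run()
  th <- fix_theta()
  # within each run epoch, consecutive boundary spacing stays near 1/7 s
  for (i in seq_len(min(3, nrow(f$runs)))) {
    b <- th$boundaries[th$boundaries >= f$runs$t_start[i] &
                       th$boundaries <= f$runs$t_end[i]]
    expect_gt(length(b), 5)
    expect_true(all(diff(b) > 1 / 11 - 0.02 & diff(b) < 1 / 5 + 0.02))
  }
})
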
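test_that("adaptive smoothing reproduces hand-computed circle expansion", {
  nb <- 25
  dwell <- matrix(0, nb, nb)
  spk <- matrix(0, nb, nb)
  # centre bin (13,13): dwell 1 s; ring bins at exactly 10 cm: dwell 0.75 s
  # and 6.25 spikes each -> at r = 10 cm the circle holds d = 4, s = 25,
  # alpha/(d*sqrt(s)) = 200/(4*5) = 10, so expansion stops there, rate 6.25
  dwell[13, 13] <- 1
  for (o in list(c(4, 0), c(-4, 0), c(0, 4), c(0, -4))) {
    dwell[13 + o[1], 13 + o[2]] <- 0.75
    spk[13 + o[1], 13 + o[2]] <- 6.25
  }
  m <- placeseq:::adaptive_smooth(dwell, spk, bin_cm = 2.5, alpha = 200)
  expect_equal(m$rates[13, 13], 6.25)
})

test_that("adaptive map of homogeneous input is flat at s/d", {
  dwell <- matrix(1, 10, 10)
  spk <- matrix(2, 10, 10)
  m <- placeseq:::adaptive_smooth(dwell, spk, 2.5, 200)
  expect_true(all(abs(m$rates - 2) < 1e-12))
  # silent cell: positive dwell everywhere, no spikes -> all rates 0
  m0 <- placeseq:::adaptive_smooth(dwell, spk * 0, 2.5, 200)
  expect_true(all(m0$rates[m0$visited] == 0))
})

test_that("directional run splitting finds constant-direction bouts", {
  g <- track_geometry(62.5)
  fs <- 50
  # alternating 6 s CW / 6 s CCW at 10 cm/s, five of each
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  dir <- ifelse((t %/% 6) %% 2 == 0, 1, -1)
  lin <- (cumsum(dir * 10 / fs)) %% g$perimeter
  runs <- split_directional_runs(lin, t, g$perimeter, min_bout = 5,
                                 speed_floor = 2.5)
  expect_equal(sum(runs$direction == "CW"), 5)
  expect_equal(sum(runs$direction == "CCW"), 5)
  # one 15 s monotone CW lap -> a single CW epoch spanning ~15 s
  t2 <- seq(0, 15 - 1 / fs, by = 1 / fs)
  runs2 <- split_directional_runs((10 * t2) %% g$perimeter, t2, g$perimeter)
  expect_equal(nrow(runs2), 1)
  expect_equal(runs2$direction, "CW")
  expect_gt(runs2$t_end - runs2$t_start, 14)
  # a 4 s bout is below the minimum and excluded
  t3 <- seq(0, 4 - 1 / fs, by = 1 / fs)
  runs3 <- split_directional_runs((10 * t3) %% g$perimeter, t3, g$perimeter)
  expect_equal(nrow(runs3), 0)
})

test_that("circular smoothing conserves mass and matches the wrapped kernel", {
  x <- numeric(100); x[40] <- 7
  sm <- circular_smooth(x, sigma_bins = 2)
  expect_equal(sum(sm), 7)
  # closed-form truncated, renormalized wrapped Gaussian
  h <- ceiling(3 * 2)
  k <- dnorm(-h:h, sd = 2); k <- k / sum(k)
  expect_equal(sm[40 + (-h:h)], 7 * k)
  # wrap-around
  y <- numeric(20); y[1] <- 1
  smy <- circular_smooth(y, 2)
  expect_equal(smy[20], smy[2])
  expect_equal(sum(smy), 1)
})

test_that("track rate maps recover generator field centres", {
  f <- fix_run()
  for (cid in c(3, 11, 22)) {
    m <- track_ratemaps(f$filtered, f$geom, cid, lin = f$lin, runs = f$runs)
    expect_false(is.null(m$CW))
    pk <- (which.max(m$CW$rates) - 0.5) * m$CW$bin_cm
    # theta compression/precession in the fixture smears fields slightly
    expect_lt(abs(circ_diff(pk, f$truth$field_centers[cid],
                            f$geom$perimeter)), 3 * m$CW$bin_cm + 1e-9)
    # total spikes recovered from unsmoothed bins
    ep <- f$runs[f$runs$direction == "CW", ]
    st <- f$filtered$spikes
    st <- st$t[st$cell_id == cid]
    expect_equal(sum(m$CW$spikes), sum(placeseq:::in_epochs(st, ep)))
  }
})

test_that("flat input gives a flat smoothed track map", {
  lin <- seq(0, 249.9, by = 0.1) # uniform coverage
  t <- seq_along(lin) * 0.02
  ep <- data.frame(t_start = 0, t_end = max(t) + 1)
  spike_t <- t[seq(1, length(t), by = 10)]
  m <- placeseq:::linear_ratemap(lin, t, spike_t, ep, 250)
  expect_lt(diff(range(m$rates)), 0.05 * mean(m$rates))
})

test_that("place-field similarity behaves like a Pearson correlation", {
  f <- fix_run()
  mA <- track_ratemaps(f$filtered, f$geom, 3, lin = f$lin, runs = f$runs)$CW
  mB <- track_ratemaps(f$filtered, f$geom, 17, lin = f$lin, runs = f$runs)$CW
  expect_equal(place_field_similarity(mA, mA), 1)
  m2 <- mA; m2$rates <- 2 * m2$rates
  expect_equal(place_field_similarity(mA, m2), 1)
  expect_equal(place_field_similarity(mA, mB),
               place_field_similarity(mB, mA))
  # hand-entered 3-bin maps with reversed rates anticorrelate exactly
  mk <- function(r) structure(list(rates = r, dwell = rep(1, 3), n_bins = 3),
                              class = "ps_linear_ratemap")
  expect_equal(place_field_similarity(mk(c(1, 2, 3)), mk(c(3, 2, 1)),
                                      min_bins = 3), -1)
  # zero variance -> missing
  expect_true(is.na(place_field_similarity(mk(c(1, 1, 1)), mk(c(1, 2, 3)),
                                           min_bins = 3)))
})

test_that("spatial information matches analytic cases", {
  mk <- function(r, d) structure(list(rates = r, dwell = d,
                                      n_bins = length(r)),
                                 class = "ps_linear_ratemap")
  expect_equal(spatial_information(mk(rep(3, 8), rep(1, 8))), 0)
  # all rate concentrated in 1 of 4 equal-dwell bins -> log2(4) bits/spike
  expect_equal(spatial_information(mk(c(4, 0, 0, 0), rep(1, 4))), 2)
  expect_true(is.na(spatial_information(mk(rep(0, 4), rep(1, 4)))))
  # a generated place cell carries > 0.15 bits/spike
  f <- fix_run()
  m <- track_ratemaps(f$filtered, f$geom, 8, lin = f$lin, runs = f$runs)$CW
  expect_gt(spatial_information(m), 0.15)
})
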
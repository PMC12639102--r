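all_stop <- function(t_max) data.frame(start = 0, end = t_max,
                                       label = "stopping")

test_that("ripple power isolates the 100-220 Hz band", {
  fs <- 1500
  t <- seq(0, 20, by = 1 / fs)
  iv <- all_stop(20)
  tone150 <- sin(2 * pi * 150 * t)
  rp <- ripple_power(tone150, fs, iv)
  # constant-amplitude tone -> near-constant envelope away from edges
  mid <- rp$t > 2 & rp$t < 18
  env_raw <- ripplefields:::smoothed_band_envelope(tone150, fs)
  expect_lt(sd(env_raw[mid]) / mean(env_raw[mid]), 0.05)
  # out-of-band tone is suppressed by >= 20 dB
  env50 <- ripplefields:::smoothed_band_envelope(sin(2 * pi * 50 * t), fs)
  expect_lt(mean(env50[mid]) / mean(env_raw[mid]), 0.1)
  # z-scoring normalizes over stopping periods
  set.seed(4)
  rp_noise <- ripple_power(rnorm(length(t)), fs, iv)
  expect_lt(abs(mean(rp_noise$z)), 1e-4)
  expect_equal(sd(rp_noise$z), 1, tolerance = 1e-3)
  expect_error(ripple_power(rnorm(100), 400, iv), "sample rate")
})

test_that("tetrode averaging happens before z-scoring", {
  fs <- 1500
  set.seed(9)
  lfp <- matrix(rnorm(fs * 10 * 3), ncol = 3)
  iv <- all_stop(10)
  rpm <- ripple_power(lfp, fs, iv)
  envs <- sapply(1:3, function(k)
    ripplefields:::smoothed_band_envelope(lfp[, k], fs))
  avg <- rowMeans(envs)
  expect_equal(rpm$z, (avg - mean(avg)) / sd(avg), tolerance = 1e-8)
  per_tet <- ripple_power(lfp, fs, iv, average = FALSE)
  expect_length(per_tet, 3L)
})

test_that("spike density histograms, smooths and z-scores population spiking", {
  iv <- all_stop(30)
  # no spikes -> flat series
  sd0 <- spike_density(list(a = numeric(0)), c(0, 30), iv)
  expect_equal(var(sd0$z), 0)
  set.seed(10)
  hom <- list(a = sort(runif(3000, 0, 30)), b = sort(runif(3000, 0, 30)))
  sdh <- spike_density(hom, c(0, 30), iv)
  expect_lt(abs(mean(sdh$z)), 1e-3)
  # a planted 100-spike volley stands out at the right time
  volley <- sort(c(runif(600, 0, 30), runif(100, 14.95, 15)))
  sdv <- spike_density(list(a = volley), c(0, 30), iv)
  expect_lt(abs(sdv$t[which.max(sdv$z)] - 15), 0.15)
  expect_gt(max(sdv$z), 3)
})

test_that("threshold events honor duration, boundary and merge rules", {
  mk_series <- function(z, fs = 1000) {
    t <- (seq_along(z) - 1) / fs
    structure(data.frame(t = t, z = z), fs = fs, kind = "test",
              mean = 0, sd = 1, class = c("signal_series", "data.frame"))
  }
  expect_equal(nrow(detect_events(mk_series(rep(0, 1000)), 2, 0.015, 0.05)),
               0L)
  # one 20 ms excursion to z = 3: one ripple event, zero burst events
  z <- rep(-0.1, 1000)
  z[500:519] <- 3
  z[480:499] <- 0.5; z[520:539] <- 0.5   # shoulders above 0
  s <- mk_series(z)
  rip <- detect_events(s, 2, 0.015, 0.05)
  expect_equal(nrow(rip), 1L)
  expect_equal(rip$peak_z, 3)
  # boundaries extend to the mean (z <= 0) crossings
  expect_lt(rip$start, 0.48)
  expect_gte(rip$end, 0.539)
  expect_equal(nrow(detect_events(s, 3, 0.05, NULL)), 0L)
  # two excursions 30 ms apart merge under the 50 ms rule
  z2 <- rep(-0.1, 1000)
  z2[300:319] <- 3; z2[350:369] <- 2.5
  merged <- detect_events(mk_series(z2), 2, 0.015, 0.05)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$peak_z, 3)
  unmerged <- detect_events(mk_series(z2), 2, 0.015, merge_gap = 0.001)
  expect_equal(nrow(unmerged), 2L)
  # detection commutes with time translation
  sh <- detect_events(mk_series(c(rep(-0.1, 100), z2[1:900])), 2, 0.015, 0.05)
  expect_equal(sh$peak_t, merged$peak_t + 0.1, tolerance = 1e-9)
})

test_that("binomial tetrode bound matches exact CDF enumeration", {
  expect_equal(min_confident_detectors(64, 0.11, 0.95), 11)
  expect_equal(min_confident_detectors(10, 0, 0.95), 0)
  expect_equal(min_confident_detectors(10, 0.5, 0.95), 8)
  # brute-force enumeration oracle for a sweep of n and p
  for (n in c(5, 16, 64)) for (p in c(0.05, 0.11, 0.4)) {
    cdf <- cumsum(choose(n, 0:n) * p^(0:n) * (1 - p)^(n:0))
    expect_equal(min_confident_detectors(n, p, 0.95),
                 (0:n)[which(cdf >= 0.95)[1]])
  }
  # monotone in p and in level
  ks <- vapply(c(0.05, 0.1, 0.2, 0.4), function(p)
    min_confident_detectors(32, p), numeric(1))
  expect_true(all(diff(ks) >= 0))
  expect_lte(min_confident_detectors(32, 0.2, 0.9),
             min_confident_detectors(32, 0.2, 0.99))
  expect_error(min_confident_detectors(10, 1.2), "p_false")
})

test_that("independence expectations multiply marginals", {
  e <- expected_joint_fractions(0.7, 0.7)
  expect_equal(e$p_neither, 0.09)
  expect_equal(e$p_both, 0.49)
  expect_equal(expected_joint_fractions(0, 0), list(p_neither = 1, p_both = 0))
  expect_equal(expected_joint_fractions(1, 1), list(p_neither = 0, p_both = 1))
})

test_that("band power separates ripple and sharp-wave bands", {
  fs <- 1500
  t <- seq(0, 2, by = 1 / fs)
  tone150 <- sin(2 * pi * 150 * t)
  expect_gt(band_power(tone150, fs, c(100, 220)) /
              max(band_power(tone150, fs, c(4, 12)), 1e-12), 100)
  tone8 <- sin(2 * pi * 8 * t)
  expect_gt(band_power(tone8, fs, c(4, 12)),
            band_power(tone8, fs, c(100, 220)))
  expect_equal(band_power(rep(0, 3000), fs, c(100, 220)), 0)
  expect_error(band_power(tone150[1:20], fs, c(4, 12)), "2 cycles")
})

test_that("replay labeling distinguishes planted ripples from noise", {
  fs <- 1500
  dur <- 60
  n <- dur * fs
  iv <- all_stop(dur)
  replay <- data.frame(start = 30, end = 30.3)
  set.seed(15)
  noise <- ripplefields:::pink_noise(n, 20)
  # strong 150 Hz transient mid-replay
  amp <- calibrate_ripple_amplitude(fs, 20, target_z = 6, seed = 3)
  tr <- ripplefields:::ripple_transient(fs, 150, 0.08)
  lfp <- noise
  i0 <- round(30.15 * fs)
  lfp[i0:(i0 + length(tr) - 1)] <- lfp[i0:(i0 + length(tr) - 1)] + amp * tr
  rp <- ripple_power(lfp, fs, iv)
  rev_ <- detect_events(rp, 2, 0.015, 0.05)
  flat <- spike_density(list(a = sort(runif(2000, 0, dur))), c(0, dur), iv)
  bev <- detect_events(flat, 3, 0.05, NULL)
  lb <- label_replay(replay, rev_, bev, rp, flat, iv, replay, seed = 2)
  expect_true(lb$has_ripple)
  expect_true(lb$class %in% c("ripple_only", "both"))
  # noise-only LFP: almost never classified as ripple-bearing (20 seeds)
  rp0 <- ripple_power(noise, fs, iv)
  rev0 <- detect_events(rp0, 2, 0.015, 0.05)
  wins <- seq(5, 50, length.out = 20)
  cls <- vapply(seq_along(wins), function(i) {
    label_replay(data.frame(start = wins[i], end = wins[i] + 0.3),
                 rev0[0, ], bev, rp0, flat, iv,
                 data.frame(start = wins[i], end = wins[i] + 0.3),
                 seed = 20 + i)$class
  }, character(1))
  expect_gte(mean(cls == "rippleless_burstless"), 0.8)
  # replay covering all stopping time starves the snippet test
  expect_error(label_replay(data.frame(start = 0, end = dur), rev_, bev,
                            rp, flat, iv, data.frame(start = 0, end = dur),
                            seed = 1),
               "insufficient")
})

test_that("tetrode counting is bounded and exact for planted coincidence", {
  replay <- list(start = 10, end = 10.5)
  ev_hit <- data.frame(peak_t = 10.2, peak_z = 5, start = 10.1, end = 10.4)
  ev_miss <- data.frame(peak_t = 3, peak_z = 5, start = 2.9, end = 3.2)
  evs <- c(replicate(48, ev_hit, simplify = FALSE),
           replicate(16, ev_miss, simplify = FALSE))
  expect_equal(count_detecting_tetrodes(replay, evs), 48L)
  expect_equal(count_detecting_tetrodes(replay, list(ev_miss)), 0L)
  expect_lte(count_detecting_tetrodes(replay, evs), length(evs))
})

test_that("matched downsampling equalizes joint feature histograms", {
  set.seed(30)
  fa <- cbind(rnorm(200, 10), rnorm(200, 5))
  # identical groups: everything retained
  mm <- matched_downsample(fa, fa, seed = 1)
  expect_equal(mm$keep_a, 1:200)
  expect_equal(mm$keep_b, 1:200)
  # disjoint supports: nothing retained
  fb <- cbind(rnorm(50, 100), rnorm(50, 50))
  m2 <- matched_downsample(fa, fb, seed = 1)
  expect_length(m2$keep_a, 0)
  # min rule within a shared cell
  a1 <- cbind(rep(1, 5), rep(1, 5))
  b1 <- cbind(rep(1, 3), rep(1, 3))
  m3 <- matched_downsample(a1, b1, seed = 1)
  expect_length(m3$keep_a, 3)
  expect_length(m3$keep_b, 3)
})
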
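env45 <- make_environment()

test_that("event fields accumulate signal per bin normalized by occupancy", {
  # constant signal -> field constant on occupied bins
  paths <- straight_paths(5, seed = 1)
  t_max <- max(vapply(paths, function(p) max(p$t), numeric(1))) + 1
  const <- ar_signal(t_max, seed = 2)
  const$z <- rep(2.5, nrow(const))
  ef <- compute_event_field(paths, const, env45)
  expect_equal(unique(round(ef$field[ef$valid], 9)), 2.5)
  expect_equal(unique(round(ef$smoothed[ef$valid], 6)), 2.5)
  # occupancy counts samples; invalid bins stay NA
  expect_equal(sum(ef$occupancy), sum(vapply(paths, nrow, numeric(1))))
  expect_true(all(is.na(ef$smoothed[!ef$valid])))
  # random signal matches a per-bin accumulation oracle
  sig <- ar_signal(t_max, seed = 3)
  ef2 <- compute_event_field(paths, sig, env45)
  ssum <- matrix(0, 45, 45); occ <- matrix(0, 45, 45)
  for (p in paths) {
    z <- approx(sig$t, sig$z, p$t)$y
    for (j in seq_len(nrow(p))) {
      b <- coord_to_bin(env45, p$x[j], p$y[j])
      ssum[b$ix, b$iy] <- ssum[b$ix, b$iy] + z[j]
      occ[b$ix, b$iy] <- occ[b$ix, b$iy] + 1
    }
  }
  expect_equal(ef2$field[occ > 0], (ssum / occ)[occ > 0], tolerance = 1e-10)
  expect_error(compute_event_field(list(), sig, env45), "no replays")
  # invariance to replay ordering
  ef3 <- compute_event_field(rev(paths), sig, env45)
  expect_equal(ef3$field, ef2$field, tolerance = 1e-12)
})

test_that("circular shuffles preserve the signal multiset and calibrate", {
  paths <- straight_paths(12, seed = 4)
  t_max <- max(vapply(paths, function(p) max(p$t), numeric(1))) + 1
  sig <- ar_signal(t_max, seed = 5)
  fn <- field_null(paths, sig, env45, "si", n = 30, seed = 6)
  expect_length(fn$null, 30)
  expect_true(fn$p >= 0 && fn$p <= 1)
  # shuffling preserves total signal mass: rebuild one shuffle by hand
  zv <- ripplefields:::signal_at_paths(paths, sig)
  concat <- unlist(zv)
  for (off in c(3, 57)) {
    rot <- concat[((seq_along(concat) - 1 + off) %% length(concat)) + 1]
    expect_equal(sort(rot), sort(concat))
  }
  # a zone-locked signal is detected with high significance
  zone_sig <- sig
  for (p in paths) {
    inz <- sqrt((p$x - 30)^2 + (p$y - 30)^2) < 12
    if (any(inz)) {
      idx <- round(p$t[inz] * attr(sig, "fs")) + 1
      zone_sig$z[idx] <- zone_sig$z[idx] + 6
    }
  }
  fn2 <- field_null(paths, zone_sig, env45, "si", n = 100, seed = 7)
  expect_lte(fn2$p, 0.02)
  expect_error(field_null(paths[1], sig, env45, "si"), "2 replays")
})

test_that("split-half stability tracks signal consistency across halves", {
  paths <- straight_paths(20, seed = 8)
  t_max <- max(vapply(paths, function(p) max(p$t), numeric(1))) + 1
  # identical halves: duplicate first half paths and signal values
  zv <- lapply(paths, function(p) rep(1, nrow(p)))
  half <- paths[1:10]
  same <- c(half, half)
  zs <- lapply(same, function(p) rnorm(nrow(p)))
  zs[11:20] <- zs[1:10]
  expect_equal(split_half_stability(same, zs, env45), 1, tolerance = 1e-9)
  # signal concentrated in opposite corners per half -> negative correlation
  corner <- function(p, cx, cy) 5 * (sqrt((p$x - cx)^2 + (p$y - cy)^2) < 25)
  z2 <- c(lapply(paths[1:10], corner, cx = 10, cy = 10),
          lapply(paths[11:20], corner, cx = 80, cy = 80))
  expect_lt(split_half_stability(paths, z2, env45), 0)
})

test_that("temporal shift destroys zone-locked spatial information", {
  paths <- straight_paths(60, seed = 9, t_gap = 5)
  paths <- lapply(paths, function(p) { p$t <- p$t + 1; p })  # headroom for shifts
  t_max <- max(vapply(paths, function(p) max(p$t), numeric(1))) + 2
  sig <- ar_signal(t_max, seed = 10)
  for (p in paths) {
    inz <- sqrt((p$x - 60)^2 + (p$y - 30)^2) < 12
    if (any(inz)) {
      idx <- round(p$t[inz] * attr(sig, "fs")) + 1
      sig$z[idx] <- sig$z[idx] + 6
    }
  }
  curve <- temporal_shift_curve(paths, sig, env45, c(-0.2, 0, 0.2))
  ef <- compute_event_field(paths, sig, env45)
  expect_equal(curve$si[curve$shift_s == 0], event_field_si(ef),
               tolerance = 1e-12)
  expect_gt(curve$si[2], curve$si[1])
  expect_gt(curve$si[2], curve$si[3])
  expect_error(temporal_shift_curve(paths, sig, env45, 1e6), "shift")
})

test_that("field correlation and near-rat exclusion behave geometrically", {
  paths <- straight_paths(6, seed = 11)
  t_max <- max(vapply(paths, function(p) max(p$t), numeric(1))) + 1
  sig <- ar_signal(t_max, seed = 12)
  ef <- compute_event_field(paths, sig, env45)
  expect_equal(field_correlation(ef, ef), 1)
  # rat parked at a fixed point: samples within 30 cm are removed
  t <- seq(0, t_max, by = 0.005)
  rat <- ripplefields:::position_series(t, rep(45, length(t)),
                                        rep(45, length(t)), rep(0, length(t)))
  trimmed <- exclude_near_rat(paths, rat, radius = 30)
  for (p in trimmed)
    expect_true(all(sqrt((p$x - 45)^2 + (p$y - 45)^2) >= 30))
  total_kept <- sum(vapply(trimmed, nrow, numeric(1)))
  total_far <- sum(vapply(paths, function(p)
    sum(sqrt((p$x - 45)^2 + (p$y - 45)^2) >= 30), numeric(1)))
  expect_equal(total_kept, total_far)
  # a replay entirely local to the rat disappears
  local_path <- list(data.frame(t = 0.005 * (0:40), x = rep(45, 41),
                                y = rep(46, 41)))
  expect_length(exclude_near_rat(local_path, rat, 30), 0)
  far_path <- list(data.frame(t = 0.005 * (0:40), x = rep(5, 41),
                              y = rep(5, 41)))
  expect_length(exclude_near_rat(far_path, rat, 30), 1)
})

test_that("field zones are recovered for bumps and absent for uniform fields", {
  bc <- bin_centers(env45)
  bump2 <- exp(-((bc$x - 20)^2 + (bc$y - 70)^2) / (2 * 8^2)) +
    exp(-((bc$x - 70)^2 + (bc$y - 20)^2) / (2 * 8^2))
  found <- 0
  for (s in 1:5) {
    zones <- extract_field_zones(bump2, seed = s, bin_cm = 2)
    if (length(zones) == 2) {
      coms <- t(sapply(zones, `[[`, "com"))
      err1 <- min(sqrt((coms[, 1] - 20)^2 + (coms[, 2] - 70)^2))
      err2 <- min(sqrt((coms[, 1] - 70)^2 + (coms[, 2] - 20)^2))
      if (max(err1, err2) < 8) found <- found + 1
    }
  }
  expect_gte(found, 4)
  # uniform field: ~5 samples/bin, ~140 neighbors in radius 3 < 250 -> none
  expect_length(extract_field_zones(matrix(1, 45, 45), seed = 1, bin_cm = 2),
                0)
  expect_length(extract_field_zones(matrix(0, 45, 45), seed = 1, bin_cm = 2),
                0)
  # zone sample counts and boundary invariants
  zones <- extract_field_zones(bump2, seed = 1, bin_cm = 2)
  for (z in zones) {
    expect_gte(z$n_samples, 1000)
    expect_gt(nrow(z$boundary), 3)
  }
})

test_that("pass directionality flags concentrated ripple-bearing directions", {
  # zone around the arena center
  bc <- bin_centers(env45)
  zone <- list(mask = sqrt((bc$x - 45)^2 + (bc$y - 45)^2) < 20)
  dim(zone$mask) <- c(45, 45)
  # passes: straight lines through the center at chosen angles
  mk_pass <- function(th, t0) {
    d <- seq(-44, 44, by = 2)
    data.frame(t = t0 + 0.005 * seq_along(d),
               x = 45 + d * cos(th), y = 45 + d * sin(th))
  }
  angles <- c(rep(0, 6), pi / 2, pi / 4, 3 * pi / 4, rep(pi, 3))
  paths <- lapply(seq_along(angles), function(i) mk_pass(angles[i], i * 10))
  # ripples only during the eastbound (angle 0) passes
  peaks <- vapply(paths[1:6], function(p) mean(p$t), numeric(1))
  ev <- data.frame(peak_t = peaks)
  res <- pass_direction_tuning(zone, paths, ev, env45, n_shuffle = 100,
                               seed = 2)
  expect_equal(res$n_ripple_passes, 6L)
  expect_equal(res$mvl, 1, tolerance = 1e-6)
  expect_lte(res$p, 0.2)
  # direction-independent ripples: MVL not significant
  ev_all <- data.frame(peak_t = vapply(paths, function(p) mean(p$t),
                                       numeric(1)))
  res2 <- pass_direction_tuning(zone, paths, ev_all, env45, n_shuffle = 100,
                                seed = 3)
  expect_lt(res2$mvl, 1)
  # fewer than 3 passes -> NA result
  res3 <- pass_direction_tuning(zone, paths[1:2], ev, env45, seed = 4)
  expect_true(is.na(res3$mvl))
})

test_that("MVL is 1 for aligned directions and small for uniform ones", {
  expect_equal(ripplefields:::circ_mvl(rep(1.3, 10)), 1)
  set.seed(40)
  expect_lt(ripplefields:::circ_mvl(runif(100, -pi, pi)), 0.2)
})

test_that("barrier dissimilarity is -1 for identical configurations", {
  e1 <- make_environment(barrier_slot_ids = c(1, 5, 9))
  e2 <- make_environment(barrier_slot_ids = c(1, 5, 9))
  bd <- barrier_dissimilarity(e1, e2)
  expect_equal(max(abs(bd + 1)), 0, tolerance = 1e-12)
  # moving one barrier: BD > -1 only within kernel reach of the change
  e3 <- make_environment(barrier_slot_ids = c(2, 5, 9))
  bd2 <- barrier_dissimilarity(e1, e3)
  expect_true(all(bd2 >= -1))
  expect_gt(max(bd2), -1)
  changed <- which(bd2 > -1 + 1e-9, arr.ind = TRUE)
  ctr <- (changed - 0.5) * 2
  d1 <- ripplefields:::barrier_distance(e1, ctr[, 1], ctr[, 2])
  d3 <- ripplefields:::barrier_distance(e3, ctr[, 1], ctr[, 2])
  expect_lt(max(pmin(d1, d3)), 45)  # within kernel reach of some barrier
  expect_error(barrier_dissimilarity(e1, make_environment(bin_cm = 3)),
               "grids")
})

test_that("trajectory dissimilarity is -1 for identical runs, high for
           orthogonal ones", {
  t <- seq(0, 20, by = 0.005)
  horiz <- ripplefields:::position_series(
    t, 5 + (85 - 5) * (0.5 + 0.5 * sin(2 * pi * t / 20)), rep(45, length(t)),
    rep(20, length(t)))
  vert <- ripplefields:::position_series(
    t, rep(45, length(t)), 5 + (85 - 5) * (0.5 + 0.5 * sin(2 * pi * t / 20)),
    rep(20, length(t)))
  same <- trajectory_dissimilarity(horiz, horiz, env45)
  expect_equal(min(same, na.rm = TRUE), -1, tolerance = 1e-9)
  expect_lt(max(same, na.rm = TRUE), -0.99)
  ortho <- trajectory_dissimilarity(horiz, vert, env45)
  mid <- ortho[20:25, 20:25]
  expect_gt(max(mid, na.rm = TRUE), 0)
  expect_true(all(abs(ortho[!is.na(ortho)]) <= 1 + 1e-9))
})

test_that("Fisher's combined test matches the chi-square closed form", {
  expect_equal(fisher_combined(c(1, 1, 1))$p, 1)
  f <- fisher_combined(c(0.05, 0.05))
  expect_equal(f$statistic, -4 * log(0.05), tolerance = 1e-12)
  expect_equal(f$p, 0.0174787, tolerance = 1e-5)
  # single p-value is returned unchanged
  expect_equal(fisher_combined(0.32)$p, 0.32, tolerance = 1e-12)
  expect_error(fisher_combined(numeric(0)), "empty")
  expect_error(fisher_combined(c(0, 0.5)), "zero_floor")
  expect_equal(fisher_combined(c(0, 0.5), zero_floor = 0.01)$p,
               fisher_combined(c(0.01, 0.5))$p)
})
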
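# build a minimal rf_posterior-like object from explicit summaries/counts
fake_post <- function(t, x, y, m, counts = NULL, tau = 0.08) {
  d <- sqrt(diff(x)^2 + diff(y)^2)
  gap <- c(diff(t), NA)
  delta <- c(d, NA)
  delta[!is.na(gap) & abs(gap - 0.005) > 5e-4] <- NA
  structure(list(
    summary = data.frame(t = t, x_cm = x, y_cm = y, m = m, delta = delta,
                         n_spikes = 0),
    counts = counts, starts = t - tau / 2, tau = tau, stride = 0.005,
    cells = character(0)), class = "rf_posterior")
}

still_pos <- function(t_max, speed = 0) {
  t <- seq(0, t_max, by = 0.005)
  ripplefields:::position_series(t, rep(0, length(t)), rep(0, length(t)),
                                 rep(speed, length(t)))
}

test_that("validity mask applies speed, spread and jump gates", {
  n <- 50
  t <- 0.04 + 0.005 * (0:(n - 1))
  post <- fake_post(t, seq(0, 9.8, length.out = n), rep(0, n), rep(5, n))
  expect_true(all(validity_mask(post, still_pos(1))))
  # too fast everywhere
  expect_false(any(validity_mask(post, still_pos(1, speed = 6))))
  # a single 30 cm jump invalidates exactly the earlier window
  x <- c(seq(0, 4.9, length.out = 25), seq(35, 39.9, length.out = 25))
  post2 <- fake_post(t, x, rep(0, n), rep(5, n))
  mask <- validity_mask(post2, still_pos(1))
  expect_equal(which(!mask), 25L)
  # spread gate
  m <- rep(5, n); m[10] <- 11
  post3 <- fake_post(t, seq(0, 9.8, length.out = n), rep(0, n), m)
  expect_equal(which(!validity_mask(post3, still_pos(1))), 10L)
})

test_that("candidate extraction merges across small spatiotemporal gaps", {
  # two valid runs separated by a 40 ms gap; spatial gap controlled by x
  mk <- function(x_jump) {
    n1 <- 30; gapw <- 8; n2 <- 30
    t <- 0.04 + 0.005 * (0:(n1 + gapw + n2 - 1))
    x <- c(seq(0, 3, length.out = n1), rep(50, gapw),
           seq(3 + x_jump, 6 + x_jump, length.out = n2))
    m <- c(rep(5, n1), rep(30, gapw), rep(5, n2))
    fake_post(t, x, rep(0, length(t)), m)
  }
  post <- mk(10)   # 10 cm spatial gap
  mask <- validity_mask(post, still_pos(1))
  cands <- extract_and_merge(mask, post)
  expect_length(cands, 1L)
  expect_equal(cands[[1]]$merged_from, 2L)
  post2 <- mk(30)  # 30 cm gap: stays split
  cands2 <- extract_and_merge(validity_mask(post2, still_pos(1)), post2)
  expect_length(cands2, 2L)
  # chain of three pairwise-mergeable runs collapses to one
  n <- 20; gapw <- 6
  t <- 0.04 + 0.005 * (0:(3 * n + 2 * gapw - 1))
  x <- c(seq(0, 2, length.out = n), rep(50, gapw),
         seq(4, 6, length.out = n), rep(50, gapw),
         seq(8, 10, length.out = n))
  m <- c(rep(5, n), rep(30, gapw), rep(5, n), rep(30, gapw), rep(5, n))
  post3 <- fake_post(t, x, rep(0, length(t)), m)
  cands3 <- extract_and_merge(validity_mask(post3, still_pos(1)), post3)
  expect_length(cands3, 1L)
  expect_equal(cands3[[1]]$merged_from, 3L)
})

test_that("dispersion follows both conventions", {
  expect_equal(dispersion(c(0, 0), c(0, 0)), 0)
  # two points 20 cm apart: literal D = sqrt(10); rms D = 10
  expect_equal(dispersion(c(0, 20), c(0, 0), form = "literal"), sqrt(10))
  expect_equal(dispersion(c(0, 20), c(0, 0), form = "rms"), 10)
  set.seed(2)
  x <- rnorm(10, sd = 5); y <- rnorm(10, sd = 5)
  d2 <- mean((x - mean(x))^2 + (y - mean(y))^2)
  expect_equal(dispersion(x, y), sqrt(d2), tolerance = 1e-12)
  expect_equal(dispersion(x, y, "literal"),
               sqrt(mean(sqrt((x - mean(x))^2 + (y - mean(y))^2))),
               tolerance = 1e-12)
})

test_that("removing the merge step never increases accepted duration", {
  set.seed(13)
  n <- 200
  t <- 0.04 + 0.005 * (0:(n - 1))
  m <- ifelse(runif(n) < 0.7, 5, 30)
  post <- fake_post(t, cumsum(runif(n, 0, 2)), rep(0, n), m)
  mask <- validity_mask(post, still_pos(2))
  merged <- extract_and_merge(mask, post)
  unmerged <- extract_and_merge(mask, post, time_gap = -1)
  dur <- function(cands) sum(vapply(cands, function(cd) cd$end - cd$start,
                                    numeric(1)))
  expect_gte(dur(merged), dur(unmerged))
})

test_that("cell-ID shuffle passes true replays and not single-cell events", {
  b <- small_session()
  pos <- b$positions
  env <- b$env
  maps <- lapply(b$spikes, compute_rate_map, pos = pos, env = env)
  occ <- occupancy_prob(maps[[1]])
  mr <- vapply(maps, function(m) sum(m$smoothed[m$valid] * occ[m$valid]),
               numeric(1))
  si <- vapply(maps, function(m)
    tryCatch(spatial_information(m$smoothed, occ), error = function(e) 0),
    numeric(1))
  pc <- names(maps)[classify_place_cells(mr, si)]
  dec <- build_decoder(maps, pc, env)
  stopping <- detect_stopping(pos, 5)
  post <- decode_session(b$spikes, dec, c(0, b$duration_s),
                         intervals = stopping)
  mask <- validity_mask(post, pos)
  cands <- extract_and_merge(mask, post)
  # the main candidate of each true replay should pass the shuffle test
  tr <- b$ground_truth$true_replays
  tested <- 0; passed <- 0
  for (i in seq_len(nrow(tr))) {
    ov <- Filter(function(cd) cd$start < tr$end[i] && cd$end > tr$start[i],
                 cands)
    # only candidates reaching the shuffle stage (duration and D gates)
    ov <- Filter(function(cd) cd$end - cd$start > 0.1 &&
                   dispersion(cd$path$x, cd$path$y) > 12, ov)
    if (!length(ov)) next
    cd <- ov[[which.max(vapply(ov, function(c0) c0$end - c0$start,
                               numeric(1)))]]
    sh <- cell_id_shuffle_test(cd, post, dec, n = 100, seed = 7)
    tested <- tested + 1
    if (sh$p_spread <= 0.05 && sh$p_jump <= 0.05) passed <- passed + 1
  }
  expect_gte(tested, 3)
  expect_gte(passed / tested, 0.8)
  expect_error(cell_id_shuffle_test(cands[[1]], post, dec, n = 0), "shuffle")
})

test_that("detector output is invariant to cell relabeling", {
  b <- small_session()
  pos <- b$positions
  env <- b$env
  maps <- lapply(b$spikes, compute_rate_map, pos = pos, env = env)
  occ <- occupancy_prob(maps[[1]])
  mr <- vapply(maps, function(m) sum(m$smoothed[m$valid] * occ[m$valid]),
               numeric(1))
  si <- vapply(maps, function(m)
    tryCatch(spatial_information(m$smoothed, occ), error = function(e) 0),
    numeric(1))
  pc <- names(maps)[classify_place_cells(mr, si)]
  dec <- build_decoder(maps, pc, env)
  stopping <- detect_stopping(pos, 5)
  post <- decode_session(b$spikes, dec, c(0, b$duration_s),
                         intervals = stopping)
  # relabel: permute cells everywhere consistently
  perm <- sample(length(pc))
  dec2 <- build_decoder(maps[pc[perm]], pc[perm], env)
  post2 <- decode_session(b$spikes[pc[perm]], dec2, c(0, b$duration_s),
                          intervals = stopping)
  expect_equal(post2$summary$x_cm, post$summary$x_cm, tolerance = 1e-9)
  expect_equal(post2$summary$m, post$summary$m, tolerance = 1e-9)
  r1 <- detect_replays(post, pos, dec, n_shuffle = 20, seed = 3)
  r2 <- detect_replays(post2, pos, dec2, n_shuffle = 20, seed = 3)
  expect_equal(r1$start, r2$start)
  expect_equal(r1$D, r2$D, tolerance = 1e-9)
})

test_that("sessions without stopping yield no replays; accepted events
           re-satisfy the validity mask", {
  b <- small_session()
  pos <- b$positions
  maps <- lapply(b$spikes[1:20], compute_rate_map, pos = pos, env = b$env)
  dec <- build_decoder(maps, names(maps), b$env)
  # fabricate an always-running rat
  fast <- pos; fast$speed[] <- 30
  post <- decode_session(b$spikes[1:20], dec, c(0, 20))
  out <- detect_replays(post, fast, dec, seed = 1)
  expect_equal(nrow(out[out$accepted, ]), 0L)
})
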
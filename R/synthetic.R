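# Synthetic session generator. Emulates the statistical structure the
# analysis assumes: Gaussian-tuned place cells with Poisson spiking driven by
# the rat's position during run, stopping periods containing replay
# trajectories at compressed speed with spikes drawn from the fields at the
# *replayed* position, and LFP consisting of 1/f background noise plus
# ripple-band transients injected only while a replay passes through a
# designated ground-truth ripple zone. Every component consumes its own
# seed substream derived from the session seed.

#' Default synthetic-session configuration
#'
#' All rates are Hz, lengths cm, times seconds. Replay speed defaults to
#' 20 x a typical run speed of 20 cm/s; replay durations are log-normal with
#' a ~270 ms median, clipped to 0.1-1 s. The in-zone gain boost makes
#' population spiking surge where ripples are injected, so ripple and burst
#' events co-localize, as they do in recorded data.
#'
#' @return named list of generator parameters
#' @export
synthetic_config <- function() {
  list(
    duration_s = 480,
    n_cells = 150,
    n_tetrodes = 8,
    fs_lfp = 1500,
    fs_pos = 200,
    field_sd_cm = 8,
    peak_rate_meanlog = log(15), peak_rate_sdlog = 0.3,
    baseline_hz = 0.2,
    field_bias = NULL,        # list(x, y, sd_cm, frac) for over-representation
    barrier_slot_ids = c(1L, 3L, 5L, 8L, 10L, 12L),
    home_well_index = 5L,
    stop_min_s = 5, stop_max_s = 12,
    run_vmax_min = 30, run_vmax_max = 60,
    n_replays = 20,
    replay_speed_meanlog = log(400), replay_speed_sdlog = 0.2,
    replay_dur_meanlog = log(0.3), replay_dur_sdlog = 0.35,
    replay_dur_min = 0.2, replay_dur_max = 1.0,
    replay_gain = 2.5,
    zone_boost = 6,
    quiet_frac = 0.2,
    frame_rate_hz = 1.5,
    frame_dur_meanlog = log(0.28), frame_dur_sdlog = 0.3,
    ripple_zones = data.frame(x = c(25, 65), y = c(65, 25),
                              radius = c(12, 12)),
    ripple_target_z = 6,
    ripple_freq_hz = 150,
    ripple_dur_s = 0.08,
    ripple_tetrodes = NULL,   # NULL = all tetrodes receive transients
    lfp_noise_sd = 20
  )
}

# ---------------------------------------------------------------------------
# trajectory

# BFS shortest path on the bin grid with barrier-adjacent bins blocked
grid_path <- function(env, from_cm, to_cm) {
  n <- env$n_bins
  blocked <- matrix(FALSE, n, n)
  bc <- bin_centers(env)
  if (nrow(env$barriers) > 0) {
    d <- barrier_distance(env, as.vector(bc$x), as.vector(bc$y))
    blocked[] <- d < 1.5
  }
  b0 <- coord_to_bin(env, from_cm[1], from_cm[2])
  b1 <- coord_to_bin(env, to_cm[1], to_cm[2])
  src <- c(b0$ix, b0$iy); dst <- c(b1$ix, b1$iy)
  blocked[src[1], src[2]] <- FALSE; blocked[dst[1], dst[2]] <- FALSE
  prev <- matrix(0L, n, n)
  prev[src[1], src[2]] <- -1L
  queue <- matrix(src, 1)
  found <- FALSE
  while (nrow(queue) && !found) {
    nxt <- list()
    for (q in seq_len(nrow(queue))) {
      cx <- queue[q, 1]; cy <- queue[q, 2]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        vx <- cx + d[1]; vy <- cy + d[2]
        if (vx < 1 || vx > n || vy < 1 || vy > n) next
        if (blocked[vx, vy] || prev[vx, vy] != 0L) next
        prev[vx, vy] <- (cx - 1L) * n + cy
        if (vx == dst[1] && vy == dst[2]) { found <- TRUE; break }
        nxt[[length(nxt) + 1L]] <- c(vx, vy)
      }
      if (found) break
    }
    queue <- if (length(nxt)) do.call(rbind, nxt) else matrix(0, 0, 2)
  }
  if (!found && !(src[1] == dst[1] && src[2] == dst[2]))
    stop("unreachable well given barriers")
  # walk back
  path <- list(dst)
  cur <- dst
  while (!(cur[1] == src[1] && cur[2] == src[2])) {
    p <- prev[cur[1], cur[2]]
    if (p == -1L) break
    cur <- c((p - 1L) %/% n + 1L, (p - 1L) %% n + 1L)
    path[[length(path) + 1L]] <- cur
  }
  m <- do.call(rbind, rev(path))
  cbind((m[, 1] - 0.5) * env$bin_cm, (m[, 2] - 0.5) * env$bin_cm)
}

# cumulative arc-length positions along a polyline at given distances
walk_polyline <- function(poly, dists) {
  seglen <- sqrt(rowSums(diff(poly)^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  dists <- pmin(dists, total)
  i <- pmin(findInterval(dists, cum), nrow(poly) - 1L)
  frac <- (dists - cum[i]) / pmax(seglen[i], 1e-12)
  cbind(poly[i, 1] + frac * (poly[i + 1L, 1] - poly[i, 1]),
        poly[i, 2] + frac * (poly[i + 1L, 2] - poly[i, 2]))
}

#' Simulate a barrier-avoiding rat trajectory
#'
#' The rat alternates stops at wells (stationary, >= `stop_min_s` seconds)
#' with run bouts to a randomly chosen next well along a shortest
#' barrier-avoiding grid path, with a triangular speed profile peaking at a
#' per-bout maximum. Sampled at 200 Hz; reproducible by seed.
#'
#' @param env an `rf_environment`
#' @param duration_s session duration in seconds
#' @param seed RNG seed
#' @param config generator parameters (see [synthetic_config()])
#' @return a `position_series`
#' @export
simulate_trajectory <- function(env, duration_s, seed,
                                config = synthetic_config()) {
  if (duration_s <= 0) stop("duration must be positive")
  rng <- local_rng(substream(seed, "trajectory"))
  on.exit(restore_rng(rng))
  fs <- config$fs_pos
  dt <- 1 / fs
  n_target <- ceiling(duration_s * fs) + 1L
  cur_well <- env$home_well_index
  xs <- numeric(0); ys <- numeric(0)
  while (length(xs) < n_target) {
    # stop at current well
    stop_n <- round(stats::runif(1, config$stop_min_s, config$stop_max_s) * fs)
    wx <- env$wells$x[cur_well]; wy <- env$wells$y[cur_well]
    xs <- c(xs, rep(wx, stop_n)); ys <- c(ys, rep(wy, stop_n))
    if (length(xs) >= n_target) break
    # run to a new well
    nxt <- sample(setdiff(seq_len(nrow(env$wells)), cur_well), 1)
    poly <- grid_path(env, c(wx, wy),
                      c(env$wells$x[nxt], env$wells$y[nxt]))
    total <- sum(sqrt(rowSums(diff(poly)^2)))
    vmax <- stats::runif(1, config$run_vmax_min, config$run_vmax_max)
    # triangular speed profile from/to rest
    t_run <- 2 * total / vmax
    nt <- max(2L, round(t_run * fs))
    tt <- seq_len(nt) / nt
    d <- ifelse(tt < 0.5, 2 * vmax * tt^2 * t_run / 2,
                total - 2 * vmax * (1 - tt)^2 * t_run / 2)
    pts <- walk_polyline(poly, d)
    xs <- c(xs, pts[, 1]); ys <- c(ys, pts[, 2])
    cur_well <- nxt
  }
  xs <- xs[seq_len(n_target)]; ys <- ys[seq_len(n_target)]
  t <- (seq_len(n_target) - 1L) * dt
  sp <- c(0, sqrt(diff(xs)^2 + diff(ys)^2) * fs)
  position_series(t, xs, ys, sp, fs = fs)
}

# ---------------------------------------------------------------------------
# place fields and run spiking

#' Draw ground-truth place fields
#'
#' Gaussian tuning curves with log-normal peak rates and a uniform baseline.
#' Field centers are uniform over the arena unless `config$field_bias`
#' specifies over-representation (a fraction of centers drawn near given
#' points).
#'
#' @param env an `rf_environment`
#' @param seed RNG seed
#' @param config generator parameters
#' @return data.frame with `cell`, `x`, `y`, `sd_cm`, `peak_hz`,
#'   `baseline_hz`, `tetrode`
#' @export
make_cell_fields <- function(env, seed, config = synthetic_config()) {
  rng <- local_rng(substream(seed, "misc"))
  on.exit(restore_rng(rng))
  n <- config$n_cells
  cx <- stats::runif(n, 0, env$arena_cm)
  cy <- stats::runif(n, 0, env$arena_cm)
  if (!is.null(config$field_bias)) {
    fb <- config$field_bias
    pick <- stats::runif(n) < fb$frac
    j <- sample(seq_along(fb$x), sum(pick), replace = TRUE)
    cx[pick] <- pmin(env$arena_cm, pmax(0, fb$x[j] + stats::rnorm(sum(pick), 0, fb$sd_cm)))
    cy[pick] <- pmin(env$arena_cm, pmax(0, fb$y[j] + stats::rnorm(sum(pick), 0, fb$sd_cm)))
  }
  data.frame(cell = sprintf("c%03d", seq_len(n)), x = cx, y = cy,
             sd_cm = config$field_sd_cm,
             peak_hz = stats::rlnorm(n, config$peak_rate_meanlog,
                                     config$peak_rate_sdlog),
             baseline_hz = config$baseline_hz,
             tetrode = rep_len(seq_len(config$n_tetrodes), n),
             stringsAsFactors = FALSE)
}

# field rate of every cell at positions (vectorized over positions)
field_rate <- function(fields, i, x, y) {
  fields$baseline_hz[i] + fields$peak_hz[i] *
    exp(-((x - fields$x[i])^2 + (y - fields$y[i])^2) /
          (2 * fields$sd_cm[i]^2))
}

#' Simulate run spiking from ground-truth fields
#'
#' Inhomogeneous Poisson spikes drawn per 5 ms position sample, times
#' jittered uniformly within the sample. In `"field"` mode the rate is each
#' cell's field evaluated at the rat's position throughout. In
#' `"reallocate"` mode, field-driven firing applies only while the rat is
#' moving (speed above `still_threshold`); during immobility each cell
#' instead fires diffusely at its field's spatial mean rate (spatially
#' uninformative background, as in quiet wakefulness), and inside
#' `exclude_intervals` (planted replay epochs) this background is suppressed
#' entirely so that replay spiking re-expresses, rather than adds to, the
#' population rate.
#'
#' @param fields data.frame from [make_cell_fields()]
#' @param pos a `position_series`
#' @param seed RNG seed
#' @param mode `"field"` (default) or `"reallocate"`
#' @param exclude_intervals data.frame (start, end) where background firing
#'   is suppressed (reallocate mode only)
#' @param still_threshold immobility speed threshold, cm/s
#' @param env optional `rf_environment` used to evaluate spatial mean rates
#'   (defaults to a 90 cm arena grid)
#' @param quiet_frac fraction of the spatial mean rate expressed as diffuse
#'   background during immobility (reallocate mode)
#' @return named list of sorted spike-time vectors
#' @export
simulate_run_spikes <- function(fields, pos, seed, mode = c("field", "reallocate"),
                                exclude_intervals = NULL,
                                still_threshold = 5, env = NULL,
                                quiet_frac = 0.2) {
  mode <- match.arg(mode)
  if (any(fields$peak_hz < 0) || any(fields$baseline_hz < 0))
    stop("negative rates in ground-truth fields")
  rng <- local_rng(substream(seed, "run_spikes"))
  on.exit(restore_rng(rng))
  dt <- 1 / attr(pos, "fs")
  still <- pos$speed <= still_threshold
  excl <- if (!is.null(exclude_intervals) && nrow(exclude_intervals))
    in_intervals(pos$t, exclude_intervals[order(exclude_intervals$start), ])
  else rep(FALSE, nrow(pos))
  if (mode == "reallocate") {
    if (is.null(env)) env <- make_environment()
    bc <- bin_centers(env)
  }
  out <- vector("list", nrow(fields))
  names(out) <- fields$cell
  for (i in seq_len(nrow(fields))) {
    r <- field_rate(fields, i, pos$x, pos$y)
    if (mode == "reallocate") {
      mean_rate <- mean(field_rate(fields, i, as.vector(bc$x),
                                   as.vector(bc$y)))
      r[still] <- quiet_frac * mean_rate
      r[excl] <- 0
    }
    k <- stats::rpois(length(r), r * dt)
    idx <- which(k > 0)
    if (!length(idx)) { out[[i]] <- numeric(0); next }
    times <- rep(pos$t[idx], k[idx]) + stats::runif(sum(k[idx]), 0, dt)
    out[[i]] <- sort(times)
  }
  out
}

# ---------------------------------------------------------------------------
# replays + LFP

pink_noise <- function(n, sd) {
  # 1/f amplitude shaping of white Gaussian noise via FFT; computed at a
  # fast composite length and truncated (prime lengths make fft quadratic)
  m <- stats::nextn(n, c(2, 3, 5))
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  f <- c(1, seq_len(m - 1))
  f <- pmin(f, m - f + 1)  # two-sided frequency index
  W <- W / sqrt(f)
  x <- Re(stats::fft(W, inverse = TRUE)) / m
  x <- x[seq_len(n)]
  x * sd / stats::sd(x)
}

ripple_transient <- function(fs, freq, dur_s) {
  n <- max(2L, round(dur_s * fs))
  tt <- seq_len(n) / fs
  env_w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))  # Hann envelope
  env_w * sin(2 * pi * freq * tt)
}

#' Calibrate ripple transient amplitude to a target z-score
#'
#' Runs the analysis pipeline's own ripple-power computation (band-pass,
#' analytic-signal magnitude, 80 ms Gaussian smoothing) on a reference noise
#' trace and on a unit-amplitude transient, and returns the raw amplitude
#' that yields the requested z-score after smoothing.
#'
#' @param fs LFP sample rate (Hz)
#' @param noise_sd background noise SD
#' @param target_z desired post-smoothing z-score of the transient peak
#' @param freq transient carrier frequency (Hz)
#' @param dur_s transient duration (s)
#' @param seed RNG seed for the reference noise trace
#' @return scalar amplitude
#' @export
calibrate_ripple_amplitude <- function(fs, noise_sd, target_z, freq = 150,
                                       dur_s = 0.08, seed = 1) {
  rng <- local_rng(substream(seed, "lfp") + 1L)
  noise <- pink_noise(round(60 * fs), noise_sd)
  restore_rng(rng)
  all_iv <- data.frame(start = 0, end = 60)
  rp <- ripple_power(noise, fs, stopping = all_iv)
  sigma_n <- attr(rp, "sd")
  # unit transient embedded in silence, same pipeline (un-z-scored envelope)
  pad <- round(fs)
  sig <- c(rep(0, pad), ripple_transient(fs, freq, dur_s), rep(0, pad))
  env_u <- smoothed_band_envelope(sig, fs)
  target_z * sigma_n / max(env_u)
}

#' Simulate replay trajectories, replay spiking and LFP
#'
#' Each replay is a constant-speed straight path reflecting at the arena
#' walls, lasting 0.1-1 s, placed inside stopping intervals. Replay spikes
#' are Poisson draws from the ground-truth fields evaluated at the replayed
#' position, scaled by `replay_gain` and boosted by `zone_boost` while the
#' path is inside a ripple zone. The LFP is 1/f background noise per tetrode;
#' a ripple-band transient (amplitude calibrated to `ripple_target_z`) is
#' injected at the midpoint of every zone crossing, on all (or a configured
#' subset of) tetrodes. Replays that never enter a zone receive no transient;
#' their fraction is recorded as `design_fraction_rippleless`.
#'
#' @param fields data.frame from [make_cell_fields()]
#' @param env an `rf_environment`
#' @param stop_intervals data.frame (start, end) of stopping periods
#' @param duration_s session duration (s)
#' @param seed RNG seed
#' @param config generator parameters
#' @return list with `replay_spikes` (per-cell), `lfp` (samples x tetrodes
#'   matrix), `fs_lfp`, and `ground_truth` (true replays with paths, zones,
#'   per-tetrode injected ripple times, design_fraction_rippleless)
#' @export
simulate_replays_and_lfp <- function(fields, env, stop_intervals, duration_s,
                                     seed, config = synthetic_config()) {
  if (nrow(stop_intervals) == 0L) stop("stop intervals must be nonempty")
  zones <- config$ripple_zones
  if (!is.null(zones) && nrow(zones)) {
    if (any(zones$x < 0 | zones$x > env$arena_cm |
            zones$y < 0 | zones$y > env$arena_cm))
      stop("ripple zones outside arena")
  } else zones <- data.frame(x = numeric(0), y = numeric(0),
                             radius = numeric(0))
  rng <- local_rng(substream(seed, "replays"))
  dt <- 0.005
  # draw replay windows inside stopping intervals, non-overlapping
  margin <- 0.2
  durs <- pmin(config$replay_dur_max,
               pmax(config$replay_dur_min,
                    stats::rlnorm(config$n_replays,
                                  config$replay_dur_meanlog,
                                  config$replay_dur_sdlog)))
  iv <- stop_intervals[stop_intervals$end - stop_intervals$start >
                         max(durs) + 2 * margin, , drop = FALSE]
  if (nrow(iv) == 0L) stop("no stopping interval long enough for replays")
  placed <- data.frame(start = numeric(0), end = numeric(0))
  starts <- numeric(config$n_replays)
  for (r in seq_len(config$n_replays)) {
    ok <- FALSE
    for (try in 1:200) {
      j <- sample.int(nrow(iv), 1,
                      prob = iv$end - iv$start - durs[r] - 2 * margin)
      s <- stats::runif(1, iv$start[j] + margin,
                        iv$end[j] - margin - durs[r])
      if (!nrow(placed) ||
          all(s + durs[r] + 0.5 < placed$start | s > placed$end + 0.5)) {
        ok <- TRUE; break
      }
    }
    if (!ok) stop("could not place replays without overlap; ",
                  "increase stopping time or reduce n_replays")
    placed <- rbind(placed, data.frame(start = s, end = s + durs[r]))
    starts[r] <- s
  }
  ord <- order(starts)
  starts <- starts[ord]; durs <- durs[ord]
  # replay paths: constant speed, reflecting at walls
  speeds <- stats::rlnorm(config$n_replays, config$replay_speed_meanlog,
                          config$replay_speed_sdlog)
  paths <- vector("list", config$n_replays)
  for (r in seq_len(config$n_replays)) {
    nstep <- max(2L, round(durs[r] / dt))
    tt <- starts[r] + (seq_len(nstep) - 1L) * dt
    x0 <- stats::runif(1, 5, env$arena_cm - 5)
    y0 <- stats::runif(1, 5, env$arena_cm - 5)
    th <- stats::runif(1, 0, 2 * pi)
    step <- speeds[r] * dt
    raw_x <- x0 + cos(th) * step * (seq_len(nstep) - 1L)
    raw_y <- y0 + sin(th) * step * (seq_len(nstep) - 1L)
    # reflect into [0, arena]
    refl <- function(v) {
      p <- 2 * env$arena_cm
      v <- v %% p
      ifelse(v > env$arena_cm, p - v, v)
    }
    paths[[r]] <- data.frame(t = tt, x = refl(raw_x), y = refl(raw_y))
  }
  # zone membership + injected transients
  in_zone_fn <- function(px, py) {
    if (!nrow(zones)) return(rep(FALSE, length(px)))
    inz <- rep(FALSE, length(px))
    for (z in seq_len(nrow(zones)))
      inz <- inz | (sqrt((px - zones$x[z])^2 + (py - zones$y[z])^2) <=
                      zones$radius[z])
    inz
  }
  transient_times <- numeric(0)
  replay_has_zone <- logical(config$n_replays)
  for (r in seq_len(config$n_replays)) {
    inz <- in_zone_fn(paths[[r]]$x, paths[[r]]$y)
    paths[[r]]$in_zone <- inz
    replay_has_zone[r] <- any(inz)
    if (any(inz)) {
      rl <- rle(inz)
      e <- cumsum(rl$lengths); s <- e - rl$lengths + 1L
      for (q in which(rl$values)) {
        mid <- paths[[r]]$t[(s[q] + e[q]) %/% 2]
        transient_times <- c(transient_times, mid)
      }
    }
  }
  # replay spikes from fields at replayed position
  replay_spikes <- stats::setNames(vector("list", nrow(fields)), fields$cell)
  for (i in seq_len(nrow(fields))) replay_spikes[[i]] <- numeric(0)
  for (r in seq_len(config$n_replays)) {
    p <- paths[[r]]
    gain <- config$replay_gain * ifelse(p$in_zone, config$zone_boost, 1)
    for (i in seq_len(nrow(fields))) {
      rate <- field_rate(fields, i, p$x, p$y) * gain
      k <- stats::rpois(length(rate), pmax(rate, 0) * dt)
      idx <- which(k > 0)
      if (length(idx))
        replay_spikes[[i]] <- c(replay_spikes[[i]],
                                rep(p$t[idx], k[idx]) +
                                  stats::runif(sum(k[idx]), 0, dt))
    }
  }
  # stationary reactivation frames: spatially coherent population events at
  # a fixed location, same population rate as replay. They give stopping
  # periods replay-scale spike-density fluctuations (so burst labeling is
  # calibrated against a realistic background) but carry no trajectory, so
  # the dispersion gate rejects them.
  frames <- data.frame(start = numeric(0), end = numeric(0),
                       x = numeric(0), y = numeric(0))
  stop_total <- sum(stop_intervals$end - stop_intervals$start)
  n_frames <- stats::rpois(1, config$frame_rate_hz * stop_total /
                             (1 + config$frame_rate_hz * 0.3))
  if (n_frames > 0) {
    w <- stop_intervals$end - stop_intervals$start
    for (q in seq_len(n_frames)) {
      fdur <- stats::rlnorm(1, config$frame_dur_meanlog,
                            config$frame_dur_sdlog)
      for (try in 1:50) {
        j <- sample.int(nrow(stop_intervals), 1, prob = w)
        fs0 <- stats::runif(1, stop_intervals$start[j],
                            max(stop_intervals$start[j],
                                stop_intervals$end[j] - fdur))
        fe0 <- min(fs0 + fdur, stop_intervals$end[j])
        # keep frames clear of replays and each other so the detector's
        # 50 ms merge gap cannot chain them into pseudo-trajectories
        sep <- 0.2
        clash <- any(fs0 < placed$end + sep & fe0 > placed$start - sep) ||
          (nrow(frames) &&
             any(fs0 < frames$end + sep & fe0 > frames$start - sep))
        if (!clash) {
          frames <- rbind(frames,
                          data.frame(start = fs0, end = fe0,
                                     x = stats::runif(1, 5, env$arena_cm - 5),
                                     y = stats::runif(1, 5, env$arena_cm - 5)))
          break
        }
      }
    }
  }
  if (nrow(frames)) {
    for (q in seq_len(nrow(frames))) {
      tt <- seq(frames$start[q], frames$end[q], by = dt)
      for (i in seq_len(nrow(fields))) {
        rate <- field_rate(fields, i, frames$x[q], frames$y[q]) *
          config$replay_gain
        k <- stats::rpois(length(tt), rate * dt)
        idx <- which(k > 0)
        if (length(idx))
          replay_spikes[[i]] <- c(replay_spikes[[i]],
                                  rep(tt[idx], k[idx]) +
                                    stats::runif(sum(k[idx]), 0, dt))
      }
    }
  }
  replay_spikes <- lapply(replay_spikes, sort)
  restore_rng(rng)
  # LFP: pink noise + calibrated transients
  rng <- local_rng(substream(seed, "lfp"))
  fs <- config$fs_lfp
  n_samp <- ceiling(duration_s * fs) + 1L
  amp <- if (length(transient_times))
    calibrate_ripple_amplitude(fs, config$lfp_noise_sd,
                               config$ripple_target_z,
                               config$ripple_freq_hz, config$ripple_dur_s,
                               seed = seed) else 0
  tet_set <- config$ripple_tetrodes
  if (is.null(tet_set)) tet_set <- seq_len(config$n_tetrodes)
  lfp <- matrix(0, n_samp, config$n_tetrodes)
  burst <- ripple_transient(fs, config$ripple_freq_hz, config$ripple_dur_s)
  half <- length(burst) %/% 2
  for (k in seq_len(config$n_tetrodes)) {
    tr <- pink_noise(n_samp, config$lfp_noise_sd)
    if (k %in% tet_set) {
      for (t0 in transient_times) {
        i0 <- round(t0 * fs) - half
        idx <- seq_along(burst) + i0
        ok <- idx >= 1 & idx <= n_samp
        tr[idx[ok]] <- tr[idx[ok]] + amp * burst[ok]
      }
    }
    lfp[, k] <- tr
  }
  restore_rng(rng)
  true_replays <- data.frame(start = starts, end = starts + durs,
                             speed = speeds, enters_zone = replay_has_zone)
  gt <- list(
    true_replays = true_replays,
    replay_paths = paths,
    ripple_zones = zones,
    ripple_times = stats::setNames(
      lapply(seq_len(config$n_tetrodes), function(k)
        if (k %in% tet_set) sort(transient_times) else numeric(0)),
      paste0("t", seq_len(config$n_tetrodes))),
    design_fraction_rippleless = mean(!replay_has_zone),
    frames = frames,
    transient_amplitude = amp)
  list(replay_spikes = replay_spikes, lfp = lfp, fs_lfp = fs,
       ground_truth = gt)
}

#' Generate a complete synthetic session
#'
#' Chains environment construction, trajectory simulation, run spiking,
#' replay + LFP synthesis, and merges run and replay spikes per cell.
#'
#' @param seed session seed (expanded into per-component substreams)
#' @param config generator parameters, see [synthetic_config()]
#' @return a session bundle: list with `positions`, `spikes`, `cells`
#'   (tetrode assignment), `lfp`, `fs_lfp`, `env`, `ground_truth`,
#'   `duration_s`, `seed`
#' @export
make_session <- function(seed, config = synthetic_config()) {
  env <- make_environment(barrier_slot_ids = config$barrier_slot_ids,
                          home_well_index = config$home_well_index)
  pos <- simulate_trajectory(env, config$duration_s, seed, config)
  fields <- make_cell_fields(env, seed, config)
  stops <- detect_stopping(pos, 5)
  rl <- simulate_replays_and_lfp(fields, env, stops, config$duration_s,
                                 seed, config)
  gt0 <- rl$ground_truth
  run_spikes <- simulate_run_spikes(
    fields, pos, seed, mode = "reallocate",
    exclude_intervals = rbind(gt0$true_replays[, c("start", "end")],
                              gt0$frames[, c("start", "end")]),
    env = env, quiet_frac = config$quiet_frac)
  spikes <- stats::setNames(lapply(fields$cell, function(cn)
    sort(c(run_spikes[[cn]], rl$replay_spikes[[cn]]))), fields$cell)
  gt <- rl$ground_truth
  gt$cell_fields <- fields
  list(positions = pos, spikes = spikes,
       cells = data.frame(cell = fields$cell, tetrode = fields$tetrode,
                          stringsAsFactors = FALSE),
       lfp = rl$lfp, fs_lfp = rl$fs_lfp, env = env, ground_truth = gt,
       duration_s = config$duration_s, seed = seed, config = config)
}
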
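# Ripple / spike-density fields over replayed space: event-conditioned
# spatial maps normalized by replay occupancy, circular-permutation null
# models, split-half stability, temporal-shift curves, density-based field
# zones, pass directionality, and environment-comparison measures.

#' @export
print.event_field <- function(x, ...) {
  cat(sprintf("<event_field> %d x %d bins, %d occupied (%d samples)\n",
              nrow(x$field), ncol(x$field), sum(x$valid),
              sum(x$occupancy)))
  invisible(x)
}

# interpolate a signal series at each replay path's timestamps
signal_at_paths <- function(paths, series, shift = 0) {
  lapply(paths, function(p) {
    z <- stats::approx(series$t, series$z, p$t + shift)$y
    if (anyNA(z)) stop("time shift exceeds the available signal")
    z
  })
}

# accumulate an event field from paths and per-path signal values
event_field_from_z <- function(paths, zvals, env, sd_cm = 8) {
  n <- env$n_bins
  allx <- unlist(lapply(paths, `[[`, "x"), use.names = FALSE)
  ally <- unlist(lapply(paths, `[[`, "y"), use.names = FALSE)
  allz <- unlist(zvals, use.names = FALSE)
  b <- coord_to_bin(env, allx, ally)
  ok <- !is.na(b$ix) & !is.na(b$iy)
  lin <- (b$iy[ok] - 1L) * n + b$ix[ok]
  occ <- matrix(tabulate(lin, nbins = n * n), n, n)
  ssum <- matrix(0, n, n)
  acc <- rowsum(allz[ok], lin)
  ssum[as.integer(rownames(acc))] <- acc
  valid <- occ > 0L
  f <- ssum / occ
  f[!valid] <- NA_real_
  sm <- smooth_map(f, valid, sd_cm = sd_cm, bin_cm = env$bin_cm,
                   kernel_cm = env$arena_cm)
  structure(list(field = f, smoothed = sm, occupancy = occ, valid = valid,
                 bin_cm = env$bin_cm, sd_cm = sd_cm),
            class = "event_field")
}

#' Event-conditioned spatial field (ripple field / spike density field)
#'
#' The signal (z-scored ripple power or spike density) is interpolated to
#' each replay path's timestamps; per 2-cm bin, interpolated samples over
#' all replay visits are summed and divided by the replay occupancy (number
#' of samples) of the bin, then smoothed with the renormalized 8-cm Gaussian
#' kernel. Bins never visited by replay are invalid.
#'
#' @param paths list of replay paths (data.frames with t, x, y at the replay
#'   sample rate)
#' @param series a `signal_series`
#' @param env an `rf_environment`
#' @param sd_cm smoothing SD (cm)
#' @param sample_hz optional resampling of paths before accumulation (e.g.
#'   20 for coarse replay timescale); NULL keeps the native 200 Hz sampling
#' @return an `event_field` with `field` (unsmoothed), `smoothed`,
#'   `occupancy`, `valid`
#' @export
compute_event_field <- function(paths, series, env, sd_cm = 8,
                                sample_hz = NULL) {
  if (!length(paths)) stop("no replays to build a field from")
  if (!is.null(sample_hz)) {
    paths <- lapply(paths, function(p) {
      tt <- seq(p$t[1], p$t[nrow(p)], by = 1 / sample_hz)
      data.frame(t = tt, x = stats::approx(p$t, p$x, tt)$y,
                 y = stats::approx(p$t, p$y, tt)$y)
    })
  }
  z <- signal_at_paths(paths, series)
  event_field_from_z(paths, z, env, sd_cm)
}

#' Spatial information of an event field
#'
#' Uses the replay occupancy as the occupancy distribution and the smoothed
#' field as the intensity; negative (below-baseline) field values are floored
#' at zero so the information sum is defined.
#'
#' @param ef an `event_field`
#' @return bits per unit signal
#' @export
event_field_si <- function(ef) {
  f <- ef$smoothed
  f[is.finite(f) & f < 0] <- 0
  if (sum(f[ef$valid]) <= 0) return(0)  # no positive mass: no information
  p <- ef$occupancy / sum(ef$occupancy[ef$valid])
  p[!ef$valid] <- NA_real_
  spatial_information(f, p)
}

#' Split-half stability of an event field
#'
#' Fields are built from the first and second halves of replays in
#' chronological order; the statistic is the Pearson correlation over bins
#' occupied in both halves.
#'
#' @param paths replay paths in session order
#' @param zvals per-path signal values (as produced internally by
#'   [compute_event_field()]); alternatively pass a `signal_series` via
#'   `series`
#' @param env an `rf_environment`
#' @param series optional `signal_series` used when `zvals` is NULL
#' @return correlation (NA if no co-occupied bins)
#' @export
split_half_stability <- function(paths, zvals = NULL, env, series = NULL) {
  if (length(paths) < 2L) stop("need at least 2 replays")
  if (is.null(zvals)) zvals <- signal_at_paths(paths, series)
  h <- floor(length(paths) / 2)
  f1 <- event_field_from_z(paths[1:h], zvals[1:h], env)
  f2 <- event_field_from_z(paths[(h + 1):length(paths)],
                           zvals[(h + 1):length(paths)], env)
  rate_map_correlation(f1$smoothed, f2$smoothed)
}

#' Circular-permutation null for event-field statistics
#'
#' Concatenates the per-replay signal samples (in replay order), circularly
#' rotates the concatenation by a random offset per shuffle, reassigns the
#' rotated values to the replay paths, and recomputes the field statistic.
#' The shuffle preserves the multiset of signal values exactly while
#' destroying the alignment between signal and replayed location.
#'
#' @param paths replay paths
#' @param series a `signal_series`
#' @param env an `rf_environment`
#' @param statistic `"si"`, `"stability"`, or `"cor"` (correlation against
#'   `reference`)
#' @param reference matrix used when `statistic = "cor"`
#' @param n number of shuffles (default 200)
#' @param seed RNG seed
#' @return list with `observed`, `null` (length-n vector), and `p` =
#'   fraction of shuffles >= observed
#' @export
field_null <- function(paths, series, env,
                       statistic = c("si", "stability", "cor"),
                       reference = NULL, n = 200, seed = 1) {
  statistic <- match.arg(statistic)
  if (length(paths) < 2L) stop("need at least 2 replays")
  zvals <- signal_at_paths(paths, series)
  stat_fn <- switch(statistic,
    si = function(p, z) event_field_si(event_field_from_z(p, z, env)),
    stability = function(p, z) split_half_stability(p, z, env),
    cor = {
      if (is.null(reference)) stop("reference map required")
      function(p, z) rate_map_correlation(
        event_field_from_z(p, z, env)$smoothed, reference)
    })
  observed <- stat_fn(paths, zvals)
  lens <- lengths(zvals)
  concat <- unlist(zvals, use.names = FALSE)
  N <- length(concat)
  idx_end <- cumsum(lens)
  rng <- local_rng(seed)
  offsets <- sample.int(N - 1L, n, replace = TRUE)
  restore_rng(rng)
  null <- vapply(offsets, function(off) {
    rot <- concat[((seq_len(N) - 1L + off) %% N) + 1L]
    zs <- lapply(seq_along(lens), function(i)
      rot[(idx_end[i] - lens[i] + 1L):idx_end[i]])
    stat_fn(paths, zs)
  }, numeric(1))
  list(observed = observed, null = null, p = mean(null >= observed))
}

#' Spatial information as a function of signal time shift
#'
#' @param paths replay paths
#' @param series a `signal_series`
#' @param env an `rf_environment`
#' @param shifts_s numeric vector of shifts (s), e.g. seq(-0.5, 0.5, 0.05)
#' @return data.frame with `shift_s`, `si`
#' @export
temporal_shift_curve <- function(paths, series, env, shifts_s) {
  si <- vapply(shifts_s, function(s) {
    z <- signal_at_paths(paths, series, shift = s)
    event_field_si(event_field_from_z(paths, z, env))
  }, numeric(1))
  data.frame(shift_s = shifts_s, si = si)
}

#' Correlation between two spatial fields
#'
#' Pearson correlation over co-occupied bins; significance comes from
#' applying [field_null()] with `statistic = "cor"` to one of the fields.
#'
#' @param a,b `event_field`s or matrices
#' @return correlation (NA if undefined)
#' @export
field_correlation <- function(a, b) {
  if (inherits(a, "event_field")) a <- a$smoothed
  if (inherits(b, "event_field")) b <- b$smoothed
  rate_map_correlation(a, b)
}

#' Remove replay portions near the rat
#'
#' Path samples within `radius` of the rat's concurrent position are
#' dropped; events fragment into contiguous retained pieces.
#'
#' @param paths replay paths
#' @param pos a `position_series`
#' @param radius cm (default 30)
#' @return list of trimmed paths (possibly more or fewer than input)
#' @export
exclude_near_rat <- function(paths, pos, radius = 30) {
  out <- list()
  for (p in paths) {
    rx <- stats::approx(pos$t, pos$x, p$t, rule = 2)$y
    ry <- stats::approx(pos$t, pos$y, p$t, rule = 2)$y
    keep <- sqrt((p$x - rx)^2 + (p$y - ry)^2) >= radius
    if (!any(keep)) next
    r <- rle(keep)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (q in which(r$values))
      out[[length(out) + 1L]] <- p[starts[q]:ends[q], , drop = FALSE]
  }
  out
}

#' Extract field zones by density-based clustering
#'
#' The field is treated as a discrete probability distribution and resampled
#' `n_samples` times; samples are clustered with DBSCAN semantics (radius
#' `eps_bins` bins, `min_pts` minimum neighbors). Clusters with at least
#' `min_cluster` samples are kept; a zone's member bins are those whose
#' (lightly smoothed) sample density reaches `level` of the cluster's peak
#' density, and the boundary polyline is the corresponding level set.
#'
#' @param ef an `event_field` (or matrix + `bin_cm`)
#' @param seed RNG seed
#' @param n_samples resample count (default 10000)
#' @param eps_bins DBSCAN radius in bins (default 3)
#' @param min_pts DBSCAN minimum neighbors (default 250)
#' @param min_cluster minimum samples per kept cluster (default 1000)
#' @param level boundary level as fraction of peak density (default 0.3)
#' @param bin_cm bin size when `ef` is a matrix
#' @return list of zones: each has `mask` (logical matrix), `boundary`
#'   (data.frame x, y in cm), `n_samples`, `com` (c(x, y) cm)
#' @export
extract_field_zones <- function(ef, seed = 1, n_samples = 10000,
                                eps_bins = 3, min_pts = 250,
                                min_cluster = 1000, level = 0.3,
                                bin_cm = NULL) {
  if (inherits(ef, "event_field")) {
    bin_cm <- ef$bin_cm
    f <- ef$smoothed
  } else f <- ef
  if (is.null(bin_cm)) stop("bin_cm required for matrix input")
  w <- f
  w[!is.finite(w) | w < 0] <- 0
  if (sum(w) <= 0) return(list())
  rng <- local_rng(substream(seed, "zones"))
  idx <- sample.int(length(w), n_samples, replace = TRUE,
                    prob = as.vector(w))
  restore_rng(rng)
  counts <- matrix(tabulate(idx, nbins = length(w)), nrow(f), ncol(f))
  labels <- dbscan_grid(counts, eps_bins, min_pts)
  zones <- list()
  for (c0 in sort(unique(labels[labels > 0]))) {
    inC <- labels == c0
    nS <- sum(counts[inC])
    if (nS < min_cluster) next
    dens <- counts
    dens[!inC] <- 0
    dens <- smooth_map(dens, matrix(TRUE, nrow(f), ncol(f)),
                       sd_cm = bin_cm, bin_cm = bin_cm,
                       kernel_cm = 10 * bin_cm)
    pk <- max(dens)
    mask <- dens >= level * pk
    ctr <- (seq_len(nrow(f)) - 0.5) * bin_cm
    cl <- grDevices::contourLines(ctr, ctr, dens, levels = level * pk)
    boundary <- if (length(cl))
      data.frame(x = cl[[1]]$x, y = cl[[1]]$y)
    else data.frame(x = numeric(0), y = numeric(0))
    bins <- which(inC, arr.ind = TRUE)
    wts <- counts[inC]
    com <- c(sum((bins[, 1] - 0.5) * bin_cm * wts),
             sum((bins[, 2] - 0.5) * bin_cm * wts)) / sum(wts)
    zones[[length(zones) + 1L]] <- list(mask = mask, boundary = boundary,
                                        n_samples = nS, com = com)
  }
  zones
}

# circular mean angle and mean vector length of a set of angles
circ_mean <- function(theta) Arg(mean(exp(1i * theta)))
circ_mvl <- function(theta) Mod(mean(exp(1i * theta)))

# passes of replay paths through a zone mask: maximal in-zone runs with
# sufficient in-zone path length
zone_passes <- function(zone, paths, env, min_len = 30) {
  passes <- list()
  for (ri in seq_along(paths)) {
    p <- paths[[ri]]
    b <- coord_to_bin(env, p$x, p$y)
    inz <- !is.na(b$ix) & zone$mask[cbind(b$ix, b$iy)]
    if (!any(inz)) next
    r <- rle(inz)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (q in which(r$values)) {
      i0 <- starts[q]; i1 <- ends[q]
      if (i1 - i0 < 2L) next
      seg <- p[i0:i1, ]
      len <- sum(sqrt(diff(seg$x)^2 + diff(seg$y)^2))
      if (len < min_len) next
      ang <- atan2(diff(seg$y), diff(seg$x))
      passes[[length(passes) + 1L]] <-
        list(replay = ri, t_start = seg$t[1], t_end = seg$t[nrow(seg)],
             direction = circ_mean(ang), length_cm = len)
    }
  }
  passes
}

#' Directional tuning of ripple occurrence in a field zone
#'
#' Each qualifying pass (a replay crossing the zone with at least `min_len`
#' cm of in-zone path) gets one direction (circular mean of its segment
#' angles) and a has-ripple flag (a ripple event peak during the crossing).
#' The statistic is the mean vector length (MVL) of ripple-bearing pass
#' directions; the null circularly shifts ripple peak times within the
#' concatenated replay timeline and recomputes the MVL.
#'
#' @param zone a zone from [extract_field_zones()]
#' @param paths replay paths
#' @param ripple_events event table (uses `peak_t`)
#' @param env an `rf_environment`
#' @param n_shuffle shuffles (default 200)
#' @param seed RNG seed
#' @param min_len minimum in-zone pass length (cm, default 30)
#' @return list with `mvl` (ripple-bearing passes), `mvl_no_ripple`, `p`,
#'   `n_passes`, `n_ripple_passes`, `directions`; all-NA when fewer than 3
#'   passes qualify
#' @export
pass_direction_tuning <- function(zone, paths, ripple_events, env,
                                  n_shuffle = 200, seed = 1, min_len = 30) {
  passes <- zone_passes(zone, paths, env, min_len)
  if (length(passes) < 3L)
    return(list(mvl = NA_real_, mvl_no_ripple = NA_real_, p = NA_real_,
                n_passes = length(passes), n_ripple_passes = 0L,
                directions = numeric(0)))
  dirs <- vapply(passes, `[[`, numeric(1), "direction")
  # concatenated replay timeline for the circular shift
  seg_start <- vapply(paths, function(p) p$t[1], numeric(1))
  seg_end <- vapply(paths, function(p) p$t[nrow(p)], numeric(1))
  seg_len <- seg_end - seg_start
  cum0 <- cumsum(c(0, seg_len[-length(seg_len)]))
  total <- sum(seg_len)
  to_concat <- function(tt) {
    j <- vapply(tt, function(t1) {
      w <- which(t1 >= seg_start & t1 <= seg_end)
      if (length(w)) w[1] else NA_integer_
    }, integer(1))
    ifelse(is.na(j), NA_real_, cum0[j] + tt - seg_start[j])
  }
  from_concat <- function(cc) {
    j <- findInterval(cc, cum0)
    seg_start[j] + (cc - cum0[j])
  }
  peaks <- ripple_events$peak_t
  pk_c <- to_concat(peaks)
  pk_c <- pk_c[!is.na(pk_c)]
  mvl_for_peaks <- function(peak_times) {
    has <- vapply(passes, function(ps)
      any(peak_times >= ps$t_start & peak_times <= ps$t_end), logical(1))
    if (sum(has) == 0L) return(c(NA_real_, NA_real_, 0))
    c(circ_mvl(dirs[has]),
      if (any(!has)) circ_mvl(dirs[!has]) else NA_real_,
      sum(has))
  }
  obs <- mvl_for_peaks(from_concat(pk_c))
  rng <- local_rng(substream(seed, "shuffle"))
  offs <- stats::runif(n_shuffle, 0, total)
  restore_rng(rng)
  null <- vapply(offs, function(off)
    mvl_for_peaks(from_concat((pk_c + off) %% total))[1], numeric(1))
  list(mvl = obs[1], mvl_no_ripple = obs[2],
       p = mean(null >= obs[1], na.rm = TRUE),
       n_passes = length(passes), n_ripple_passes = as.integer(obs[3]),
       directions = dirs)
}

#' Barrier dissimilarity map between two environments
#'
#' Each environment's barrier indicator (bins overlapping barriers) is
#' convolved with a 2D Gaussian kernel (10 cm SD) into a barrier potential
#' b(x). The dissimilarity at bin i is the L2 difference of the two
#' potentials over the 4 nearest bins, normalized by ||2h|| (the Euclidean
#' norm of twice the kernel, the largest attainable difference), minus 1 —
#' so BD = -1 wherever the local barrier structure is identical.
#'
#' @param env_i,env_j two `rf_environment`s on the same grid
#' @param sd_cm kernel SD (default 10)
#' @return matrix of BD values
#' @export
barrier_dissimilarity <- function(env_i, env_j, sd_cm = 10) {
  if (env_i$n_bins != env_j$n_bins || env_i$bin_cm != env_j$bin_cm)
    stop("environments use different grids")
  n <- env_i$n_bins
  pot <- function(env) {
    ind <- matrix(0, n, n)
    ind[barrier_bin_mask(env)] <- 1
    smooth_map(ind, matrix(TRUE, n, n), sd_cm = sd_cm,
               bin_cm = env$bin_cm, kernel_cm = env$arena_cm,
               renormalize = FALSE)
  }
  bI <- pot(env_i); bJ <- pot(env_j)
  hw <- floor(env_i$arena_cm / env_i$bin_cm / 2)
  k1 <- gaussian_kernel_1d(sd_cm / env_i$bin_cm, hw)
  h2 <- outer(k1, k1)
  norm2h <- sqrt(sum((2 * h2)^2))
  d2 <- matrix(0, n, n)
  for (off in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    # shifted copies; edge bins reuse their own value for missing neighbors
    xs <- pmin(pmax(seq_len(n) + off[1], 1L), n)
    ys <- pmin(pmax(seq_len(n) + off[2], 1L), n)
    d2 <- d2 + (bI[xs, ys] - bJ[xs, ys])^2
  }
  sqrt(d2) / norm2h - 1
}

#' Trajectory dissimilarity map between two sessions
#'
#' For each bin, the distribution of movement-segment angles within
#' `radius` of the bin center is histogrammed for each session; the value is
#' the negative correlation between the two angle histograms. Bins with no
#' nearby segments in either session are invalid (NA).
#'
#' @param pos_i,pos_j `position_series` for the two sessions
#' @param env shared environment
#' @param radius neighborhood radius (cm, default 8)
#' @param n_angle_bins histogram resolution (default 16)
#' @param min_speed only segments while moving faster than this (cm/s)
#' @return matrix of dissimilarity values in \[-1, 1\]
#' @export
trajectory_dissimilarity <- function(pos_i, pos_j, env, radius = 8,
                                     n_angle_bins = 16, min_speed = 5) {
  seg_data <- function(pos) {
    dx <- diff(pos$x); dy <- diff(pos$y)
    mov <- pos$speed[-length(pos$speed)] > min_speed &
      (abs(dx) + abs(dy)) > 0
    list(x = (pos$x[-length(pos$x)] + pos$x[-1])[mov] / 2,
         y = (pos$y[-length(pos$y)] + pos$y[-1])[mov] / 2,
         ang = atan2(dy[mov], dx[mov]))
  }
  sI <- seg_data(pos_i); sJ <- seg_data(pos_j)
  n <- env$n_bins
  brks <- seq(-pi, pi, length.out = n_angle_bins + 1)
  ctr <- (seq_len(n) - 0.5) * env$bin_cm
  hist_at <- function(s, cx, cy) {
    near <- (s$x - cx)^2 + (s$y - cy)^2 <= radius^2
    if (!any(near)) return(NULL)
    tabulate(findInterval(s$ang[near], brks, rightmost.closed = TRUE),
             nbins = n_angle_bins)
  }
  out <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    hI <- hist_at(sI, ctr[i], ctr[j])
    hJ <- hist_at(sJ, ctr[i], ctr[j])
    if (is.null(hI) || is.null(hJ)) next
    if (stats::sd(hI) == 0 || stats::sd(hJ) == 0) next
    out[i, j] <- -stats::cor(hI, hJ)
  }
  out
}

#' Fisher's combined probability test
#'
#' X = -2 sum(log p) compared against chi-square with 2k degrees of
#' freedom.
#'
#' @param p_values vector of p-values in (0, 1]
#' @param zero_floor optional floor substituted for zero p-values (e.g.
#'   1/(n_shuffles + 1)); zeros without a floor are an error
#' @return list with `statistic`, `df`, `p`
#' @export
fisher_combined <- function(p_values, zero_floor = NULL) {
  if (!length(p_values)) stop("empty p-value vector")
  if (any(p_values <= 0)) {
    if (is.null(zero_floor)) stop("zero p-values require a zero_floor")
    p_values[p_values <= 0] <- zero_floor
  }
  if (any(p_values > 1)) stop("p-values must be in (0, 1]")
  X <- -2 * sum(log(p_values))
  df <- 2 * length(p_values)
  list(statistic = X, df = df,
       p = stats::pchisq(X, df, lower.tail = FALSE))
}
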
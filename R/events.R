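# Ripple-power and population-burst signals, threshold event detection,
# ripple/burst-less replay classification, and the tetrode-count confidence
# analysis.

# analytic signal via the FFT construction (zero out negative frequencies);
# zero-padded to a fast composite length so fft stays O(n log n), then
# truncated back (padding only perturbs the first/last few samples)
analytic_signal <- function(x) {
  n0 <- length(x)
  n <- stats::nextn(n0, c(2, 3, 5))
  x <- c(x, rep(0, n - n0))
  X <- stats::fft(x)
  h <- rep(0, n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  (stats::fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

# band-pass + analytic-signal magnitude + Gaussian smoothing (no z-scoring)
smoothed_band_envelope <- function(lfp, fs, band = c(100, 220),
                                   smooth_sd = 0.08, kernel_s = 1) {
  bf <- signal::butter(3, band / (fs / 2), type = "pass")
  filt <- as.numeric(signal::filtfilt(bf, lfp))
  env <- Mod(analytic_signal(filt))
  smooth_series(env, smooth_sd, fs, kernel_s)
}

new_signal_series <- function(t, z, kind, fs, mu, sdv, tetrode = NA) {
  structure(data.frame(t = t, z = z),
            kind = kind, fs = fs, mean = mu, sd = sdv, tetrode = tetrode,
            class = c("signal_series", "data.frame"))
}

#' Ripple power of an LFP trace
#'
#' Band-pass filters the trace to 100-220 Hz, takes the magnitude of the
#' analytic signal, smooths with a Gaussian kernel (80 ms SD, 1 s width) and
#' z-scores using mean/SD computed from stopping periods only. For the
#' tetrode-averaged variant pass a multi-column matrix: smoothed envelopes
#' are averaged across tetrodes first and z-scoring happens after averaging.
#'
#' @param lfp numeric vector (one tetrode) or samples x tetrodes matrix
#' @param fs sample rate (Hz); must be at least 440 Hz
#' @param stopping data.frame (start, end) of stopping periods used for the
#'   z-scoring statistics
#' @param band frequency band, Hz
#' @param smooth_sd Gaussian smoothing SD (s)
#' @param average if `lfp` is a matrix: average across tetrodes (default
#'   TRUE); otherwise a list of per-tetrode series is returned
#' @return a `signal_series` (t, z) or a list of them
#' @export
ripple_power <- function(lfp, fs, stopping, band = c(100, 220),
                         smooth_sd = 0.08, average = TRUE) {
  if (fs < 2 * band[2]) stop("sample rate too low for the requested band")
  zscore <- function(s, t) {
    m <- in_intervals(t, stopping)
    if (!any(m)) stop("no samples inside stopping periods")
    mu <- mean(s[m]); sdv <- stats::sd(s[m])
    list(z = (s - mu) / sdv, mu = mu, sd = sdv)
  }
  if (is.matrix(lfp)) {
    t <- (seq_len(nrow(lfp)) - 1) / fs
    envs <- apply(lfp, 2, smoothed_band_envelope, fs = fs, band = band,
                  smooth_sd = smooth_sd)
    if (average) {
      avg <- rowMeans(envs)
      zz <- zscore(avg, t)
      return(new_signal_series(t, zz$z, "ripple_power_mean", fs, zz$mu, zz$sd))
    }
    return(lapply(seq_len(ncol(envs)), function(k) {
      zz <- zscore(envs[, k], t)
      new_signal_series(t, zz$z, "ripple_power_tetrode", fs, zz$mu, zz$sd,
                        tetrode = k)
    }))
  }
  t <- (seq_along(lfp) - 1) / fs
  env <- smoothed_band_envelope(lfp, fs, band, smooth_sd)
  zz <- zscore(env, t)
  new_signal_series(t, zz$z, "ripple_power_tetrode", fs, zz$mu, zz$sd)
}

#' Population spike density
#'
#' Sums spikes from all clusters in 1 ms non-overlapping bins, applies the
#' same Gaussian smoothing as ripple power (80 ms SD, 1 s kernel), and
#' z-scores with stopping-period statistics.
#'
#' @param spikes named list of spike-time vectors (all accepted clusters,
#'   not just place cells)
#' @param t_range session time range `c(t0, t1)` (s)
#' @param stopping data.frame (start, end) of stopping periods
#' @param bin_s histogram bin (default 1 ms)
#' @param smooth_sd Gaussian smoothing SD (s)
#' @return a `signal_series`
#' @export
spike_density <- function(spikes, t_range, stopping, bin_s = 0.001,
                          smooth_sd = 0.08) {
  edges <- seq(t_range[1], t_range[2] + bin_s, by = bin_s)
  all_sp <- unlist(spikes, use.names = FALSE)
  all_sp <- all_sp[all_sp >= t_range[1] & all_sp < t_range[2]]
  cnt <- if (length(all_sp))
    tabulate(findInterval(all_sp, edges), nbins = length(edges) - 1L)
  else rep(0L, length(edges) - 1L)
  fs <- 1 / bin_s
  s <- smooth_series(cnt, smooth_sd, fs, 1)
  t <- edges[-length(edges)]
  m <- in_intervals(t, stopping)
  if (!any(m)) stop("no samples inside stopping periods")
  mu <- mean(s[m]); sdv <- stats::sd(s[m])
  if (sdv == 0) sdv <- 1   # degenerate flat series
  new_signal_series(t, (s - mu) / sdv, "spike_density", fs, mu, sdv)
}

#' Detect threshold events in a z-scored series
#'
#' Events are excursions whose z-score stays above `threshold_z` for at
#' least `min_duration`; start and end are then extended outward to where
#' the series returns to its mean (first z = 0 crossing on each side).
#' Adjacent events closer than `merge_gap` are merged (used for ripples:
#' 2 SD / 15 ms / 50 ms merge; bursts use 3 SD / 50 ms and no merging).
#'
#' @param series a `signal_series`
#' @param threshold_z peak threshold (SD units)
#' @param min_duration minimum above-threshold duration (s)
#' @param merge_gap boundary gap below which adjacent events merge (s), or
#'   NULL to disable merging
#' @return data.frame with `peak_t`, `peak_z`, `start`, `end`, `kind`
#' @export
detect_events <- function(series, threshold_z = 2, min_duration = 0.015,
                          merge_gap = 0.05) {
  z <- series$z; t <- series$t
  dt <- 1 / attr(series, "fs")
  above <- z > threshold_z
  r <- rle(above)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values & r$lengths * dt >= min_duration)
  if (!length(keep))
    return(data.frame(peak_t = numeric(0), peak_z = numeric(0),
                      start = numeric(0), end = numeric(0),
                      kind = character(0)))
  neg <- which(z <= 0)
  ev <- lapply(keep, function(q) {
    i0 <- starts[q]; i1 <- ends[q]
    pk <- i0 - 1L + which.max(z[i0:i1])
    lo <- neg[neg < i0]
    hi <- neg[neg > i1]
    s <- if (length(lo)) t[max(lo)] else t[1]
    e <- if (length(hi)) t[min(hi)] else t[length(t)]
    data.frame(peak_t = t[pk], peak_z = z[pk], start = s, end = e)
  })
  ev <- do.call(rbind, ev)
  # events sharing the same zero-crossing envelope collapse to one
  ev <- ev[order(ev$start, ev$peak_t), , drop = FALSE]
  out <- ev[1, , drop = FALSE]
  for (i in seq_len(nrow(ev))[-1]) {
    gap <- ev$start[i] - out$end[nrow(out)]
    if (gap <= 0 || (!is.null(merge_gap) && gap < merge_gap)) {
      j <- nrow(out)
      out$end[j] <- max(out$end[j], ev$end[i])
      if (ev$peak_z[i] > out$peak_z[j]) {
        out$peak_z[j] <- ev$peak_z[i]; out$peak_t[j] <- ev$peak_t[i]
      }
    } else out <- rbind(out, ev[i, ])
  }
  out$kind <- attr(series, "kind")
  rownames(out) <- NULL
  out
}

# sample n snippet start times of length dur from stopping periods minus
# all replay intervals; errors if no gap is long enough
sample_snippets <- function(stopping, replays, dur, n, seed) {
  allowed <- stopping
  if (nrow(replays)) {
    pieces <- list()
    for (i in seq_len(nrow(allowed))) {
      s <- allowed$start[i]; e <- allowed$end[i]
      cuts <- replays[replays$end > s & replays$start < e, , drop = FALSE]
      cuts <- cuts[order(cuts$start), , drop = FALSE]
      cur <- s
      for (j in seq_len(nrow(cuts))) {
        if (cuts$start[j] > cur)
          pieces[[length(pieces) + 1L]] <- c(cur, cuts$start[j])
        cur <- max(cur, cuts$end[j])
      }
      if (cur < e) pieces[[length(pieces) + 1L]] <- c(cur, e)
    }
    allowed <- if (length(pieces)) {
      m <- do.call(rbind, pieces)
      data.frame(start = m[, 1], end = m[, 2])
    } else data.frame(start = numeric(0), end = numeric(0))
  }
  allowed <- allowed[allowed$end - allowed$start >= dur, , drop = FALSE]
  if (nrow(allowed) == 0L)
    stop("insufficient non-replay stopping time for ", n,
         " snippets of ", round(dur, 3), " s")
  rng <- local_rng(seed)
  w <- allowed$end - allowed$start - dur
  j <- sample.int(nrow(allowed), n, replace = TRUE, prob = w + 1e-9)
  s <- allowed$start[j] + stats::runif(n) * w[j]
  restore_rng(rng)
  s
}

series_peak <- function(series, start, end) {
  # uniform sampling -> index arithmetic instead of scanning timestamps
  fs <- attr(series, "fs")
  t0 <- series$t[1]
  n <- nrow(series)
  i0 <- max(1L, ceiling((start - t0) * fs - 1e-9) + 1L)
  i1 <- min(n, floor((end - t0) * fs - 1e-9) + 1L)
  if (i1 < i0) return(-Inf)
  max(series$z[i0:i1])
}

#' Classify a replay as ripple/burst-less or not
#'
#' A replay "contains" an event if the event's peak time falls inside
#' \[start, end). The replay additionally fails the ripple (burst) criterion
#' if its peak ripple power (spike density) exceeds the 95th percentile of
#' peaks from `n_snippets` random replay-length snippets drawn across
#' stopping periods but outside all replay times. It is ripple/burst-less
#' only if it contains no event of either kind and passes both snippet
#' tests.
#'
#' @param replay list or one-row data.frame with `start`, `end` (s)
#' @param ripple_events,burst_events event tables from [detect_events()]
#' @param ripple_series,burst_series the underlying `signal_series`
#' @param stopping stopping intervals
#' @param all_replays data.frame of all replay intervals (excluded from
#'   snippet sampling)
#' @param n_snippets number of random snippets (default 100)
#' @param seed RNG seed
#' @return list with `has_ripple`, `has_burst`, `p_snippet_ripple`,
#'   `p_snippet_burst` and `class` (one of `rippleless_burstless`,
#'   `ripple_only`, `burst_only`, `both`)
#' @export
label_replay <- function(replay, ripple_events, burst_events,
                         ripple_series, burst_series, stopping, all_replays,
                         n_snippets = 100, seed = 1) {
  dur <- replay$end - replay$start
  contains <- function(ev) nrow(ev) > 0 &&
    any(ev$peak_t >= replay$start & ev$peak_t < replay$end)
  starts <- sample_snippets(stopping, all_replays, dur, n_snippets,
                            substream(seed, "snippets"))
  snip_test <- function(series) {
    pk <- series_peak(series, replay$start, replay$end)
    null_pk <- vapply(starts, function(s) series_peak(series, s, s + dur),
                      numeric(1))
    list(exceeds = pk > stats::quantile(null_pk, 0.95, names = FALSE),
         p = mean(null_pk >= pk))
  }
  rip <- snip_test(ripple_series)
  bur <- snip_test(burst_series)
  has_ripple <- contains(ripple_events) || rip$exceeds
  has_burst <- contains(burst_events) || bur$exceeds
  cls <- if (!has_ripple && !has_burst) "rippleless_burstless"
  else if (has_ripple && has_burst) "both"
  else if (has_ripple) "ripple_only" else "burst_only"
  list(has_ripple = has_ripple, has_burst = has_burst,
       p_snippet_ripple = rip$p, p_snippet_burst = bur$p, class = cls)
}

#' Number of tetrodes detecting a ripple inside a replay
#'
#' @param replay list with `start`, `end`
#' @param per_tetrode_events list of event tables, one per tetrode
#' @return integer count
#' @export
count_detecting_tetrodes <- function(replay, per_tetrode_events) {
  sum(vapply(per_tetrode_events, function(ev)
    nrow(ev) > 0 && any(ev$peak_t >= replay$start & ev$peak_t < replay$end),
    logical(1)))
}

#' Minimum tetrode count for confident detection
#'
#' The smallest k such that the Binomial(n, p_false) CDF at k reaches
#' `level`: detections on more than k tetrodes are unlikely to be chance.
#'
#' @param n_detectors number of tetrodes
#' @param p_false per-tetrode false-detection probability
#' @param level confidence level (default 0.95)
#' @return integer k
#' @export
min_confident_detectors <- function(n_detectors, p_false, level = 0.95) {
  if (p_false < 0 || p_false > 1) stop("p_false must be in [0, 1]")
  if (n_detectors < 1) stop("need at least one detector")
  k <- 0:n_detectors
  k[which(stats::pbinom(k, n_detectors, p_false) >= level)[1]]
}

#' Expected joint ripple/burst fractions under independence
#'
#' @param p_ripple,p_burst marginal probabilities
#' @return list with `p_neither` = (1-p_r)(1-p_b) and `p_both` = p_r p_b
#' @export
expected_joint_fractions <- function(p_ripple, p_burst) {
  stopifnot(p_ripple >= 0, p_ripple <= 1, p_burst >= 0, p_burst <= 1)
  list(p_neither = (1 - p_ripple) * (1 - p_burst),
       p_both = p_ripple * p_burst)
}

#' Mean squared spectral magnitude in a band
#'
#' @param segment LFP segment (numeric vector)
#' @param fs sample rate (Hz)
#' @param band `c(lo, hi)` in Hz
#' @return scalar power
#' @export
band_power <- function(segment, fs, band) {
  n <- length(segment)
  if (n / fs < 2 / band[1])
    stop("segment shorter than 2 cycles of the band's low edge")
  P <- Mod(stats::fft(segment))^2
  f <- (seq_len(n) - 1) * fs / n
  sel <- f >= band[1] & f <= band[2] & f <= fs / 2
  if (!any(sel)) return(0)
  mean(P[sel])
}

#' Downsample two event groups to matched 2D feature histograms
#'
#' Builds a joint 2D histogram over the two features and, in every cell,
#' retains min(count_A, count_B) randomly chosen events from each group, so
#' the retained groups have identical histograms.
#'
#' @param feat_a,feat_b n x 2 matrices of features (e.g. spikes/s and active
#'   cells/s per replay)
#' @param n_bins bins per feature dimension
#' @param seed RNG seed
#' @return list with integer index vectors `keep_a`, `keep_b`
#' @export
matched_downsample <- function(feat_a, feat_b, n_bins = 10, seed = 1) {
  feat_a <- as.matrix(feat_a); feat_b <- as.matrix(feat_b)
  all1 <- c(feat_a[, 1], feat_b[, 1]); all2 <- c(feat_a[, 2], feat_b[, 2])
  br1 <- seq(min(all1), max(all1), length.out = n_bins + 1)
  br2 <- seq(min(all2), max(all2), length.out = n_bins + 1)
  cell_of <- function(f) {
    i <- pmin(pmax(findInterval(f[, 1], br1, rightmost.closed = TRUE), 1), n_bins)
    j <- pmin(pmax(findInterval(f[, 2], br2, rightmost.closed = TRUE), 1), n_bins)
    (i - 1L) * n_bins + j
  }
  ca <- cell_of(feat_a); cb <- cell_of(feat_b)
  rng <- local_rng(seed)
  keep_a <- integer(0); keep_b <- integer(0)
  for (cell in intersect(unique(ca), unique(cb))) {
    ia <- which(ca == cell); ib <- which(cb == cell)
    k <- min(length(ia), length(ib))
    keep_a <- c(keep_a, if (length(ia) == k) ia else sample(ia, k))
    keep_b <- c(keep_b, if (length(ib) == k) ib else sample(ib, k))
  }
  restore_rng(rng)
  list(keep_a = sort(keep_a), keep_b = sort(keep_b))
}
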
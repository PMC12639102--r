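# Behavioral preprocessing: position smoothing/resampling and segmentation
# into stopping and drinking (reward-consumption) periods.

position_series <- function(t, x, y, speed, speed2 = NULL, fs = 200) {
  out <- data.frame(t = t, x = x, y = y, speed = speed)
  out$speed2 <- if (is.null(speed2)) speed else speed2
  attr(out, "fs") <- fs
  class(out) <- c("position_series", "data.frame")
  out
}

# zero-phase filtering with odd-reflection padding at both ends (the plain
# filtfilt in package signal zero-pads, which leaves large edge transients)
zero_phase <- function(bf, x, pad = 500L) {
  n <- length(x)
  pad <- min(n - 1L, pad)
  front <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  back <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- as.numeric(signal::filtfilt(bf, c(front, x, back)))
  y[(pad + 1L):(pad + n)]
}

# maximal runs of TRUE -> half-open [start, end) intervals on the sample grid
runs_to_intervals <- function(t, flag, label, dt) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep))
    return(data.frame(start = numeric(0), end = numeric(0),
                      label = character(0)))
  data.frame(start = t[starts[keep]],
             end = t[ends[keep]] + dt,
             label = label)
}

#' Smooth and resample a raw position trace
#'
#' Positions (typically tracked at ~30 Hz) are low-pass filtered with a
#' zero-phase second-order Butterworth filter, speed is computed from the
#' filtered trace and smoothed a second time with a lower-cutoff filter, and
#' everything is linearly interpolated onto a uniform 200 Hz grid (5 ms
#' steps). The filter cutoffs are normalized frequencies (fraction of
#' Nyquist), following the convention of the common filter-design routines.
#' Zero-phase (forward-backward) filtering is used so that smoothing does not
#' lag the speed trace relative to spike or LFP timestamps.
#'
#' @param raw data.frame with columns `t` (s), `x`, `y` (cm)
#' @param pos_cutoff normalized cutoff for position smoothing (default 0.1)
#' @param speed_cutoff normalized cutoff for the secondary speed smoothing
#'   (default 0.02); the secondary-smoothed speed is used for drinking
#'   detection
#' @param fs_out output sample rate, Hz
#' @return a `position_series` data.frame with columns `t`, `x`, `y`,
#'   `speed` (primary smoothed speed, cm/s) and `speed2` (doubly smoothed)
#' @export
smooth_and_resample <- function(raw, pos_cutoff = 0.1, speed_cutoff = 0.02,
                                fs_out = 200) {
  if (nrow(raw) < 2L) stop("need at least 2 position samples")
  if (anyNA(raw$x) || anyNA(raw$y)) {
    # tolerate brief dropouts; refuse long gaps
    na_run <- max(rle(is.na(raw$x) | is.na(raw$y))$lengths[
      rle(is.na(raw$x) | is.na(raw$y))$values], 0)
    dt_in <- stats::median(diff(raw$t))
    if (na_run * dt_in > 1) stop("NaN runs longer than 1 s in positions")
    for (cn in c("x", "y"))
      raw[[cn]] <- stats::approx(raw$t[!is.na(raw[[cn]])],
                                 raw[[cn]][!is.na(raw[[cn]])],
                                 xout = raw$t, rule = 2)$y
  }
  bf <- signal::butter(2, pos_cutoff)
  xs <- zero_phase(bf, raw$x)
  ys <- zero_phase(bf, raw$y)
  dt_in <- diff(raw$t)
  sp <- c(0, sqrt(diff(xs)^2 + diff(ys)^2) / dt_in)
  bf2 <- signal::butter(2, speed_cutoff)
  sp2 <- zero_phase(bf2, sp)
  t_out <- seq(raw$t[1], raw$t[nrow(raw)], by = 1 / fs_out)
  position_series(
    t = t_out,
    x = stats::approx(raw$t, xs, t_out)$y,
    y = stats::approx(raw$t, ys, t_out)$y,
    speed = pmax(0, stats::approx(raw$t, sp, t_out)$y),
    speed2 = pmax(0, stats::approx(raw$t, sp2, t_out)$y),
    fs = fs_out)
}

#' Stopping periods
#'
#' Maximal half-open intervals where the (primary smoothed) rat speed is
#' below `threshold`.
#'
#' @param pos a `position_series`
#' @param threshold speed threshold in cm/s (default 5)
#' @return data.frame with columns `start`, `end` (s), `label`
#' @export
detect_stopping <- function(pos, threshold = 5) {
  dt <- 1 / attr(pos, "fs")
  runs_to_intervals(pos$t, pos$speed < threshold, "stopping", dt)
}

#' Drinking (reward-consumption) periods
#'
#' Intervals where the doubly smoothed speed drops below 1 cm/s while the rat
#' is at the rewarded well (within 6 cm).
#'
#' @param pos a `position_series`
#' @param wells data.frame with columns `x`, `y` (cm), one row per well
#' @param rewarded_well index of the rewarded well
#' @param speed_threshold cm/s (default 1)
#' @param well_radius "at well" radius in cm (default 6)
#' @return data.frame with columns `start`, `end`, `label`
#' @export
detect_drinking <- function(pos, wells, rewarded_well,
                            speed_threshold = 1, well_radius = 6) {
  rewarded_well <- as.integer(rewarded_well)
  if (rewarded_well < 1L || rewarded_well > nrow(wells))
    stop("unknown well index: ", rewarded_well)
  d <- sqrt((pos$x - wells$x[rewarded_well])^2 +
            (pos$y - wells$y[rewarded_well])^2)
  flag <- pos$speed2 < speed_threshold & d <= well_radius
  dt <- 1 / attr(pos, "fs")
  runs_to_intervals(pos$t, flag, "drinking", dt)
}

# total time covered by an interval set
interval_duration <- function(iv) sum(iv$end - iv$start)

# logical membership of times in a sorted non-overlapping interval set
in_intervals <- function(t, iv) {
  if (nrow(iv) == 0L) return(rep(FALSE, length(t)))
  i <- findInterval(t, iv$start)
  i > 0 & t < iv$end[pmax(i, 1L)]
}

#' Write / read interval sets as delimited text
#' @param iv data.frame with start, end, label
#' @param path file path
#' @export
write_intervals <- function(iv, path) {
  utils::write.table(iv, path, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
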
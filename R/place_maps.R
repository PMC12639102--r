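# Place-field analysis: rate maps on the 2-cm grid, spatial information,
# place-cell selection, cross-session stability, field centers, and summed
# population maps.

#' @export
print.spatial_map <- function(x, ...) {
  cat(sprintf("<spatial_map> %d x %d bins (%g cm), %d valid; smoothing %s\n",
              nrow(x$values), ncol(x$values), x$bin_cm, sum(x$valid),
              if (is.null(x$sd_cm)) "none" else paste0(x$sd_cm, " cm SD")))
  invisible(x)
}

new_spatial_map <- function(values, occupancy, valid, bin_cm, sd_cm = NULL,
                            smoothed = NULL) {
  structure(list(values = values, smoothed = smoothed, occupancy = occupancy,
                 valid = valid, bin_cm = bin_cm, sd_cm = sd_cm),
            class = "spatial_map")
}

#' Occupancy probability over valid bins
#' @param map a `spatial_map`
#' @return matrix summing to 1 over valid bins (NA elsewhere)
#' @export
occupancy_prob <- function(map) {
  p <- map$occupancy
  p[!map$valid] <- NA_real_
  p / sum(p[map$valid])
}

#' Compute a cell's rate map
#'
#' Spikes emitted during run (rat speed above `run_threshold`) are assigned
#' to 2-cm spatial bins via linearly interpolated position; the unsmoothed
#' rate is spike count divided by run occupancy time per bin. The smoothed
#' map convolves with an isotropic 2D Gaussian (default 8 cm SD, arena-sized
#' kernel), renormalized over visited bins so that edges and unvisited bins
#' do not bias the estimate.
#'
#' @param cell_spikes sorted spike times (s)
#' @param pos a `position_series`
#' @param env an `rf_environment`
#' @param run_threshold cm/s (default 10)
#' @param sd_cm smoothing kernel SD in cm
#' @return a `spatial_map` with `values` (unsmoothed Hz), `smoothed`,
#'   `occupancy` (s) and `valid` (visited during run)
#' @export
compute_rate_map <- function(cell_spikes, pos, env, run_threshold = 10,
                             sd_cm = 8) {
  dt <- 1 / attr(pos, "fs")
  run <- pos$speed > run_threshold
  if (!any(run)) stop("zero run time: no samples above run threshold")
  n <- env$n_bins
  occ <- matrix(0, n, n)
  b <- coord_to_bin(env, pos$x[run], pos$y[run])
  ok <- !is.na(b$ix) & !is.na(b$iy)
  tb <- table(factor(b$ix[ok], levels = 1:n), factor(b$iy[ok], levels = 1:n))
  occ <- occ + unclass(tb) * dt
  cnt <- matrix(0, n, n)
  if (length(cell_spikes)) {
    sx <- stats::approx(pos$t, pos$x, cell_spikes, rule = 2)$y
    sy <- stats::approx(pos$t, pos$y, cell_spikes, rule = 2)$y
    sv <- stats::approx(pos$t, pos$speed, cell_spikes, rule = 2)$y
    keep <- sv > run_threshold
    if (any(keep)) {
      sb <- coord_to_bin(env, sx[keep], sy[keep])
      ok <- !is.na(sb$ix) & !is.na(sb$iy)
      tbs <- table(factor(sb$ix[ok], levels = 1:n),
                   factor(sb$iy[ok], levels = 1:n))
      cnt <- cnt + unclass(tbs)
    }
  }
  valid <- occ > 0
  rate <- cnt / occ
  rate[!valid] <- NA_real_
  sm <- smooth_map(rate, valid, sd_cm = sd_cm, bin_cm = env$bin_cm,
                   kernel_cm = env$arena_cm)
  new_spatial_map(rate, occ, valid, env$bin_cm, sd_cm = sd_cm, smoothed = sm)
}

#' Spatial information of a map (bits/spike)
#'
#' SI = sum_j P(x_j) (f_j / r) log2(f_j / r) with r = sum_j P(x_j) f_j the
#' occupancy-weighted mean rate; zero-rate bins contribute zero. Computed
#' over valid bins only.
#'
#' @param f matrix of rates (or any nonnegative intensity); NA = invalid
#' @param p occupancy probability matrix, summing to 1 over valid bins
#' @return bits per spike (scalar)
#' @export
spatial_information <- function(f, p) {
  ok <- is.finite(f) & is.finite(p)
  f <- f[ok]; p <- p[ok]
  p <- p / sum(p)
  r <- sum(p * f)
  if (r <= 0) stop("mean rate is zero: spatial information undefined")
  rel <- f / r
  terms <- ifelse(rel > 0, p * rel * log2(rel), 0)
  sum(terms)
}

#' Place-cell selection
#'
#' A cell is a place cell if its occupancy-weighted mean rate exceeds 0.01 Hz
#' and its spatial information exceeds 0.5 bits/spike.
#'
#' @param mean_rate numeric vector of mean rates (Hz)
#' @param si numeric vector of spatial information (bits/spike)
#' @param rate_min,si_min the thresholds
#' @return logical vector
#' @export
classify_place_cells <- function(mean_rate, si, rate_min = 0.01,
                                 si_min = 0.5) {
  mean_rate > rate_min & si > si_min
}

#' Pearson correlation between two spatial maps
#'
#' Evaluated only at valid bins common to both maps.
#'
#' @param a,b matrices (NA = invalid) or `spatial_map`s (smoothed values
#'   used)
#' @return correlation in \[-1, 1\], or NA if fewer than 2 common bins or a
#'   map has zero variance on the common support
#' @export
rate_map_correlation <- function(a, b) {
  if (inherits(a, "spatial_map")) a <- a$smoothed
  if (inherits(b, "spatial_map")) b <- b$smoothed
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 2L) return(NA_real_)
  av <- a[ok]; bv <- b[ok]
  if (stats::sd(av) == 0 || stats::sd(bv) == 0) return(NA_real_)
  stats::cor(av, bv)
}

# barrier-overlap eligibility: "active" bins have rate density (rate per cm
# of linear bin extent) above `density_thr`; at least `frac` of active bins
# must lie >= `dist_cm` from the nearest barrier
minimal_barrier_overlap <- function(map, env, density_thr = 1, frac = 0.6,
                                    dist_cm = 4) {
  f <- map$smoothed
  act <- which(is.finite(f) & (f / map$bin_cm) > density_thr, arr.ind = TRUE)
  if (nrow(act) == 0L) return(TRUE)
  ctr <- (act - 0.5) * map$bin_cm
  d <- barrier_distance(env, ctr[, 1], ctr[, 2])
  mean(d >= dist_cm) >= frac
}

#' Cross-session place-field stability labels
#'
#' For each eligible cell (a place cell in both sessions whose rate map
#' minimally overlaps the barriers in both), the session-I map is correlated
#' with the cell's session-J map, and with `n_shuffle` maps drawn by
#' permuting cell identities in session J. A cell is stable if its
#' correlation exceeds the 95th percentile of its shuffle distribution.
#'
#' @param maps_i,maps_j named lists of `spatial_map`s for the two sessions
#'   (shared cell names)
#' @param env_i,env_j environments of the two sessions
#' @param eligible_cells character vector of cell names that are place cells
#'   in both sessions
#' @param n_shuffle number of identity permutations (default 100)
#' @param seed RNG seed
#' @return data.frame with columns `cell`, `rho`, `shuffle_q95`, `stable`
#' @export
stability_labels <- function(maps_i, maps_j, env_i, env_j, eligible_cells,
                             n_shuffle = 100, seed = 1) {
  keep <- vapply(eligible_cells, function(cn) {
    minimal_barrier_overlap(maps_i[[cn]], env_i) &&
      minimal_barrier_overlap(maps_j[[cn]], env_j)
  }, logical(1))
  cells <- eligible_cells[keep]
  if (!length(cells)) {
    warning("no eligible cells for stability analysis")
    return(data.frame(cell = character(0), rho = numeric(0),
                      shuffle_q95 = numeric(0), stable = logical(0)))
  }
  rng <- local_rng(seed)
  res <- lapply(cells, function(cn) {
    rho <- rate_map_correlation(maps_i[[cn]], maps_j[[cn]])
    others <- setdiff(names(maps_j), cn)
    shuf <- vapply(seq_len(n_shuffle), function(s) {
      rate_map_correlation(maps_i[[cn]], maps_j[[sample(others, 1)]])
    }, numeric(1))
    q95 <- stats::quantile(shuf, 0.95, na.rm = TRUE, names = FALSE)
    data.frame(cell = cn, rho = rho, shuffle_q95 = q95,
               stable = isTRUE(rho > q95))
  })
  restore_rng(rng)
  do.call(rbind, res)
}

#' Field centers via density-based clustering of map resamples
#'
#' The map is treated as a discrete probability distribution and resampled
#' `n_samples` times; sample points are clustered with DBSCAN semantics
#' (neighborhood radius `eps_bins` bins, `min_pts` minimum neighbors), and
#' each cluster's center of mass is returned.
#'
#' @param map a `spatial_map` or matrix (negative / NA values treated as 0)
#' @param seed RNG seed
#' @param n_samples number of resamples (default 2500)
#' @param eps_bins DBSCAN radius in bins (default 2.5)
#' @param min_pts DBSCAN minimum neighbors (default 50)
#' @param bin_cm bin size, required when `map` is a bare matrix
#' @return data.frame with `x_cm`, `y_cm`, `cluster_size`
#' @export
field_centers <- function(map, seed = 1, n_samples = 2500, eps_bins = 2.5,
                          min_pts = 50, bin_cm = NULL) {
  if (inherits(map, "spatial_map")) {
    bin_cm <- map$bin_cm
    map <- map$smoothed
  }
  if (is.null(bin_cm)) stop("bin_cm required for matrix input")
  w <- map
  w[!is.finite(w) | w < 0] <- 0
  if (sum(w) <= 0)
    return(data.frame(x_cm = numeric(0), y_cm = numeric(0),
                      cluster_size = integer(0)))
  rng <- local_rng(seed)
  idx <- sample.int(length(w), n_samples, replace = TRUE, prob = as.vector(w))
  restore_rng(rng)
  counts <- matrix(0L, nrow(map), ncol(map))
  tb <- tabulate(idx, nbins = length(w))
  counts[] <- tb
  labels <- dbscan_grid(counts, eps_bins, min_pts)
  cl <- sort(unique(labels[labels > 0]))
  if (!length(cl))
    return(data.frame(x_cm = numeric(0), y_cm = numeric(0),
                      cluster_size = integer(0)))
  out <- lapply(cl, function(c0) {
    bins <- which(labels == c0, arr.ind = TRUE)
    wts <- counts[labels == c0]
    data.frame(x_cm = sum((bins[, 1] - 0.5) * bin_cm * wts) / sum(wts),
               y_cm = sum((bins[, 2] - 0.5) * bin_cm * wts) / sum(wts),
               cluster_size = sum(wts))
  })
  do.call(rbind, out)
}

#' Sum place-field maps over a subset of cells
#'
#' @param maps named list of `spatial_map`s on a shared grid
#' @param subset cell names to include (default all)
#' @param smoothed use smoothed (default) or unsmoothed values
#' @return matrix (NA where no contributing map is valid)
#' @export
summed_place_field_map <- function(maps, subset = names(maps),
                                   smoothed = TRUE) {
  if (!length(subset)) stop("empty subset")
  acc <- NULL
  for (cn in subset) {
    v <- if (smoothed) maps[[cn]]$smoothed else maps[[cn]]$values
    v0 <- v; v0[!is.finite(v0)] <- 0
    if (is.null(acc)) {
      acc <- v0; anyv <- is.finite(v)
    } else {
      acc <- acc + v0; anyv <- anyv | is.finite(v)
    }
  }
  acc[!anyv] <- NA_real_
  acc
}
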
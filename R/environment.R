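#' Canonical barrier slots for the 90 x 90 cm arena
#'
#' The arena is conceptually divided into a 3 x 3 grid of 30 cm cells. The 12
#' canonical barrier slots lie on the internal walls of that grid (6
#' vertical, 6 horizontal). Choosing 6 of the 12 slots gives choose(12, 6) =
#' 924 possible configurations. Barriers are free-standing "jail-bar"
#' segments: each stops `margin_cm` short of the wall junctions, so the rat
#' can always pass around barrier ends and every configuration leaves the
#' arena fully traversable.
#'
#' @param arena_cm arena side length in cm (default 90)
#' @param margin_cm gap left at each end of a slot segment (default 5)
#' @return data.frame with columns `slot`, `x0`, `y0`, `x1`, `y1` (cm)
#' @export
barrier_slots <- function(arena_cm = 90, margin_cm = 5) {
  s <- arena_cm / 3
  seg <- list()
  k <- 1L
  # vertical internal walls at x = s and x = 2s, three segments each
  for (x in c(s, 2 * s)) {
    for (i in 0:2) {
      seg[[k]] <- c(x, i * s + margin_cm, x, (i + 1) * s - margin_cm)
      k <- k + 1L
    }
  }
  # horizontal internal walls at y = s and y = 2s
  for (y in c(s, 2 * s)) {
    for (i in 0:2) {
      seg[[k]] <- c(i * s + margin_cm, y, (i + 1) * s - margin_cm, y)
      k <- k + 1L
    }
  }
  m <- do.call(rbind, seg)
  data.frame(slot = seq_len(nrow(m)), x0 = m[, 1], y0 = m[, 2],
             x1 = m[, 3], y1 = m[, 4])
}

#' Construct the task environment
#'
#' Builds the open-field arena: a square extent tiled exactly by square bins,
#' 9 reward wells at the centers of the 3 x 3 subdivision, and transparent
#' barriers occupying a subset of the 12 canonical slots.
#'
#' @param arena_cm side length of the square arena in cm
#' @param bin_cm spatial bin size in cm (the arena side must be a multiple)
#' @param barrier_slot_ids integer vector of slot ids (subset of 1:12), or
#'   empty for a barrier-free arena
#' @param home_well_index which of the 9 wells is the Home well
#' @return an object of class `rf_environment`
#' @export
make_environment <- function(arena_cm = 90, bin_cm = 2,
                             barrier_slot_ids = integer(0),
                             home_well_index = 5L) {
  if (arena_cm <= 0 || bin_cm <= 0 || (arena_cm %% bin_cm) != 0)
    stop("arena side must be a positive multiple of the bin size")
  slots <- barrier_slots(arena_cm)
  barrier_slot_ids <- as.integer(barrier_slot_ids)
  if (anyDuplicated(barrier_slot_ids))
    stop("overlapping barrier slots: duplicated slot ids")
  if (length(barrier_slot_ids) &&
      (min(barrier_slot_ids) < 1 || max(barrier_slot_ids) > nrow(slots)))
    stop("barrier slot ids must be in 1..", nrow(slots))
  barriers <- slots[slots$slot %in% barrier_slot_ids, , drop = FALSE]
  s <- arena_cm / 3
  wells <- expand.grid(x = s * (0:2) + s / 2, y = s * (0:2) + s / 2)
  wells <- data.frame(well = 1:9, x = wells$x, y = wells$y)
  if (any(wells$x < 0 | wells$x > arena_cm | wells$y < 0 | wells$y > arena_cm))
    stop("wells outside arena")
  home_well_index <- as.integer(home_well_index)
  if (home_well_index < 1L || home_well_index > nrow(wells))
    stop("home_well_index must be in 1..9")
  n_bins <- as.integer(arena_cm / bin_cm)
  env <- list(arena_cm = arena_cm, bin_cm = bin_cm, n_bins = n_bins,
              barriers = barriers, wells = wells,
              home_well_index = home_well_index)
  class(env) <- "rf_environment"
  env
}

#' @export
print.rf_environment <- function(x, ...) {
  cat(sprintf("<rf_environment> %g x %g cm arena, %d x %d bins of %g cm\n",
              x$arena_cm, x$arena_cm, x$n_bins, x$n_bins, x$bin_cm))
  cat(sprintf("  %d barrier segment(s), home well %d of %d\n",
              nrow(x$barriers), x$home_well_index, nrow(x$wells)))
  invisible(x)
}

#' Bin-center coordinates of the arena grid
#'
#' Bin i (1-based) spans [(i-1)*bin, i*bin) cm with center at (i - 0.5)*bin.
#'
#' @param env an `rf_environment`
#' @return list with vectors `centers` (length n_bins) and matrices `x`, `y`
#'   (n_bins x n_bins) of bin-center coordinates; rows index x, columns y
#' @export
bin_centers <- function(env) {
  ctr <- (seq_len(env$n_bins) - 0.5) * env$bin_cm
  list(centers = ctr,
       x = matrix(ctr, env$n_bins, env$n_bins),
       y = matrix(ctr, env$n_bins, env$n_bins, byrow = TRUE))
}

#' Map x/y coordinates (cm) to grid bin indices
#'
#' Coordinates exactly on the upper arena edge are assigned to the last bin.
#'
#' @param env an `rf_environment`
#' @param x,y coordinates in cm
#' @return list of integer vectors `ix`, `iy` (NA outside the arena)
#' @export
coord_to_bin <- function(env, x, y) {
  f <- function(v) {
    i <- floor(v / env$bin_cm) + 1L
    i[v == env$arena_cm] <- env$n_bins
    i[v < 0 | v > env$arena_cm] <- NA_integer_
    as.integer(i)
  }
  list(ix = f(x), iy = f(y))
}

# proper segment intersection test (shared endpoints count as crossing)
segments_intersect <- function(p, q, a, b) {
  d <- function(u, v, w) (v[1] - u[1]) * (w[2] - u[2]) - (v[2] - u[2]) * (w[1] - u[1])
  d1 <- d(a, b, p); d2 <- d(a, b, q); d3 <- d(p, q, a); d4 <- d(p, q, b)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(u, v, w) {
    min(u[1], v[1]) - 1e-12 <= w[1] && w[1] <= max(u[1], v[1]) + 1e-12 &&
      min(u[2], v[2]) - 1e-12 <= w[2] && w[2] <= max(u[2], v[2]) + 1e-12
  }
  (d1 == 0 && on_seg(a, b, p)) || (d2 == 0 && on_seg(a, b, q)) ||
    (d3 == 0 && on_seg(p, q, a)) || (d4 == 0 && on_seg(p, q, b))
}

#' Count barrier crossings of a path
#'
#' @param env an `rf_environment`
#' @param x,y path coordinates in cm, in temporal order
#' @return integer number of path steps that cross a barrier segment
#' @export
count_barrier_crossings <- function(env, x, y) {
  if (nrow(env$barriers) == 0L || length(x) < 2L) return(0L)
  n <- 0L
  for (i in seq_len(length(x) - 1L)) {
    p <- c(x[i], y[i]); q <- c(x[i + 1L], y[i + 1L])
    for (j in seq_len(nrow(env$barriers))) {
      a <- c(env$barriers$x0[j], env$barriers$y0[j])
      b <- c(env$barriers$x1[j], env$barriers$y1[j])
      if (segments_intersect(p, q, a, b)) { n <- n + 1L; break }
    }
  }
  n
}

# distance from points to the nearest barrier segment (Inf if no barriers)
barrier_distance <- function(env, x, y) {
  if (nrow(env$barriers) == 0L) return(rep(Inf, length(x)))
  d <- rep(Inf, length(x))
  for (j in seq_len(nrow(env$barriers))) {
    x0 <- env$barriers$x0[j]; y0 <- env$barriers$y0[j]
    dx <- env$barriers$x1[j] - x0; dy <- env$barriers$y1[j] - y0
    len2 <- dx * dx + dy * dy
    t <- pmin(1, pmax(0, ((x - x0) * dx + (y - y0) * dy) / len2))
    d <- pmin(d, sqrt((x - (x0 + t * dx))^2 + (y - (y0 + t * dy))^2))
  }
  d
}

# logical matrix of bins whose square overlaps (comes within half a bin of)
# any barrier segment
barrier_bin_mask <- function(env) {
  bc <- bin_centers(env)
  m <- matrix(FALSE, env$n_bins, env$n_bins)
  if (nrow(env$barriers) == 0L) return(m)
  d <- barrier_distance(env, as.vector(bc$x), as.vector(bc$y))
  matrix(d <= env$bin_cm / 2 + 1e-9, env$n_bins, env$n_bins)
}
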
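# Memory-less Bayesian position decoding. The posterior over spatial bins
# given a window's spike-count vector assumes Poisson spiking, independence
# between cells and a uniform spatial prior:
#   P(x_j | k) propto prod_i f_i(x_j)^{k_i} exp(-tau f_i(x_j)).
# Everything is computed in log space and normalized over the valid bins.

#' Assemble a decoder from place-cell rate maps
#'
#' Stacks the smoothed rate maps of the selected cells over the bins valid in
#' all maps (visited bins), with a small rate floor so the log-likelihood is
#' defined everywhere.
#'
#' @param maps named list of `spatial_map`s
#' @param cells names of the cells to decode with (place cells)
#' @param env an `rf_environment`
#' @param rate_floor additive floor on rates inside the likelihood (Hz)
#' @return an `rf_decoder`: rate matrix `F` (cells x bins), bin coordinates
#'   `bx`, `by` (cm), the valid-bin mask, and cell names
#' @export
build_decoder <- function(maps, cells, env, rate_floor = 1e-4) {
  if (!length(cells)) stop("zero place cells: cannot decode")
  valid <- Reduce(`&`, lapply(maps[cells], function(m) m$valid))
  if (!any(valid)) stop("no bins valid in all maps")
  idx <- which(valid)
  bc <- bin_centers(env)
  F <- do.call(rbind, lapply(maps[cells], function(m) {
    v <- m$smoothed[idx]
    v[!is.finite(v) | v < 0] <- 0
    v + rate_floor
  }))
  rownames(F) <- cells
  structure(list(F = F, logF = log(F), bx = bc$x[idx], by = bc$y[idx],
                 valid = valid, cells = cells, rate_floor = rate_floor,
                 bin_cm = env$bin_cm),
            class = "rf_decoder")
}

#' Decode a single window
#'
#' @param k integer spike-count vector (one entry per decoder cell)
#' @param decoder an `rf_decoder` (or a bare cells x bins rate matrix)
#' @param tau window duration in seconds (default 0.08)
#' @return probability vector over the decoder's valid bins
#' @export
decode_window <- function(k, decoder, tau = 0.08) {
  F <- if (inherits(decoder, "rf_decoder")) decoder$F else decoder
  logF <- if (inherits(decoder, "rf_decoder")) decoder$logF else log(F)
  if (length(k) != nrow(F)) stop("count vector length != number of cells")
  if (any(k < 0) || any(k != floor(k))) stop("counts must be nonnegative integers")
  ll <- as.vector(k %*% logF) - tau * colSums(F)
  ll <- ll - max(ll)
  p <- exp(ll)
  s <- sum(p)
  if (!is.finite(s) || s <= 0) return(rep(NA_real_, ncol(F)))
  p / s
}

#' Posterior center of mass, spread and jump series
#'
#' @param P matrix of posterior probabilities, one row per window
#' @param bx,by bin-center coordinates (cm), one per column of `P`
#' @param convention spread convention: `"trace"` (default) uses
#'   m^2 = sum((x - x_cm)^2 + (y - y_cm)^2) P, the trace of the posterior
#'   covariance, so m is in cm and directly comparable to the 10 cm gate;
#'   `"product"` uses the literal product moment
#'   m^2 = sum((x - x_cm)^2 (y - y_cm)^2) P (units cm^2)
#' @return data.frame with `x_cm`, `y_cm`, `m`, `delta` (last delta NA)
#' @export
posterior_summaries <- function(P, bx, by,
                                convention = c("trace", "product")) {
  convention <- match.arg(convention)
  P <- as.matrix(P)
  x <- as.vector(P %*% bx)
  y <- as.vector(P %*% by)
  if (convention == "trace") {
    ex2 <- as.vector(P %*% (bx^2 + by^2))
    m <- sqrt(pmax(0, ex2 - x^2 - y^2))
  } else {
    m <- vapply(seq_len(nrow(P)), function(i) {
      sqrt(max(0, sum((bx - x[i])^2 * (by - y[i])^2 * P[i, ])))
    }, numeric(1))
  }
  d <- sqrt(diff(x)^2 + diff(y)^2)
  data.frame(x_cm = x, y_cm = y, m = m, delta = c(d, NA_real_))
}

# spike counts per cell in half-open windows [start, start + tau)
window_counts <- function(spikes, cells, starts, tau) {
  K <- matrix(0L, length(starts), length(cells))
  ends <- starts + tau
  for (ci in seq_along(cells)) {
    sp <- spikes[[cells[ci]]]
    if (!length(sp)) next
    K[, ci] <- findInterval(ends - 1e-9, sp) - findInterval(starts - 1e-9, sp)
  }
  K
}

#' Decode a session (or selected intervals) with a sliding window
#'
#' Windows of duration `tau` are advanced in `stride` steps; windows that
#' would be truncated at interval or session edges are dropped, so every
#' decoded bin shares the same tau. Window timestamps are window centers.
#'
#' @param spikes named list of sorted spike-time vectors (s)
#' @param decoder an `rf_decoder`
#' @param t_range session time range `c(t0, t1)` in seconds
#' @param intervals optional data.frame (start, end) restricting decoding to
#'   those intervals (e.g. stopping periods); windows never span interval
#'   boundaries
#' @param tau window duration (s), default 0.08
#' @param stride window step (s), default 0.005
#' @param chunk windows per processing block
#' @param convention spread convention, see [posterior_summaries()]
#' @return an `rf_posterior`: data.frame `summary` (t, x_cm, y_cm, m, delta,
#'   n_spikes), integer count matrix `counts`, plus window metadata
#' @export
decode_session <- function(spikes, decoder, t_range, intervals = NULL,
                           tau = 0.08, stride = 0.005, chunk = 4000L,
                           convention = "trace") {
  if (is.null(intervals))
    intervals <- data.frame(start = t_range[1], end = t_range[2])
  starts <- unlist(lapply(seq_len(nrow(intervals)), function(i) {
    s0 <- intervals$start[i]; s1 <- intervals$end[i]
    if (s1 - s0 < tau) return(numeric(0))
    seq(s0, s1 - tau, by = stride)
  }))
  if (!length(starts)) stop("no complete windows in the requested intervals")
  K <- window_counts(spikes, decoder$cells, starts, tau)
  n <- length(starts)
  sm <- vector("list", ceiling(n / chunk))
  for (b in seq_along(sm)) {
    i0 <- (b - 1L) * chunk + 1L
    i1 <- min(n, b * chunk)
    ll <- K[i0:i1, , drop = FALSE] %*% decoder$logF
    ll <- sweep(ll, 2, tau * colSums(decoder$F))
    ll <- ll - apply(ll, 1, max)
    P <- exp(ll)
    P <- P / rowSums(P)
    sm[[b]] <- posterior_summaries(P, decoder$bx, decoder$by, convention)
  }
  out <- do.call(rbind, sm)
  # deltas are only meaningful between windows one stride apart
  gap <- c(diff(starts), NA)
  out$delta[!is.na(gap) & abs(gap - stride) > stride / 10] <- NA_real_
  out$delta[nrow(out)] <- NA_real_
  structure(list(
    summary = data.frame(t = starts + tau / 2, out,
                         n_spikes = rowSums(K)),
    counts = K, starts = starts, tau = tau, stride = stride,
    cells = decoder$cells),
    class = "rf_posterior")
}

#' @export
print.rf_posterior <- function(x, ...) {
  cat(sprintf("<rf_posterior> %d windows (tau %g ms, stride %g ms), %d cells\n",
              nrow(x$summary), x$tau * 1000, x$stride * 1000,
              length(x$cells)))
  invisible(x)
}
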
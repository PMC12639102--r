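# Shared smoothing primitives: 1D Gaussian kernel smoothing for time series
# and edge/NA-renormalized 2D Gaussian smoothing for spatial maps.

gaussian_kernel_1d <- function(sd_samples, half_width_samples) {
  x <- seq(-half_width_samples, half_width_samples)
  k <- exp(-0.5 * (x / sd_samples)^2)
  k / sum(k)
}

#' Gaussian-smooth a uniformly sampled series
#'
#' Convolution with a truncated Gaussian kernel; the kernel is renormalized
#' near the edges so constant signals stay constant.
#'
#' @param x numeric vector
#' @param sd_s kernel standard deviation in seconds
#' @param fs sample rate (Hz)
#' @param width_s total kernel width in seconds
#' @return numeric vector, same length as `x`
#' @export
smooth_series <- function(x, sd_s, fs, width_s = 1) {
  hw <- max(1L, round(width_s * fs / 2))
  k <- gaussian_kernel_1d(sd_s * fs, hw)
  n <- length(x)
  # FFT convolution (linear, via zero-padding to a fast composite length)
  m <- stats::nextn(n + 2L * hw, c(2, 3, 5))
  K <- stats::fft(c(k, rep(0, m - length(k))))
  convolve_same <- function(v) {
    V <- stats::fft(c(v, rep(0, m - n)))
    Re(stats::fft(V * K, inverse = TRUE))[(hw + 1):(hw + n)] / m
  }
  num <- convolve_same(x)
  # exact kernel renormalization where the window is truncated at the edges
  cs <- c(0, cumsum(k))
  i <- seq_len(n)
  a <- hw + 1L - pmin(hw, i - 1L)
  b <- hw + 1L + pmin(hw, n - i)
  den <- cs[b + 1L] - cs[a]
  num / den
}

#' Smooth a spatial map with an isotropic 2D Gaussian, renormalized over
#' valid bins
#'
#' Implements edge- and missing-bin-corrected smoothing: the map is convolved
#' with the kernel restricted (and renormalized) to the valid bins, and bins
#' outside the validity mask stay invalid (NA). The isotropic kernel is
#' applied separably.
#'
#' @param values matrix of bin values (NA allowed at invalid bins)
#' @param valid logical matrix of the same shape; NULL means all finite bins
#' @param sd_cm kernel standard deviation in cm
#' @param bin_cm bin size in cm
#' @param kernel_cm total kernel width in cm (default 90, i.e. arena-sized)
#' @param renormalize correct for edges/invalid bins by renormalizing the
#'   kernel over valid bins (default TRUE); FALSE gives the plain truncated
#'   convolution used e.g. for barrier potentials
#' @return matrix of smoothed values, NA outside `valid`
#' @export
smooth_map <- function(values, valid = NULL, sd_cm = 8, bin_cm = 2,
                       kernel_cm = 90, renormalize = TRUE) {
  if (is.null(valid)) valid <- is.finite(values)
  stopifnot(all(dim(values) == dim(valid)))
  hw <- max(1L, floor(kernel_cm / bin_cm / 2))
  k <- gaussian_kernel_1d(sd_cm / bin_cm, hw)
  n <- nrow(values); m <- ncol(values)
  # banded convolution matrices for rows and columns
  band <- function(sz) {
    B <- matrix(0, sz, sz)
    for (i in seq_len(sz)) {
      j <- (i - hw):(i + hw)
      ok <- j >= 1 & j <= sz
      B[i, j[ok]] <- k[ok]
    }
    B
  }
  Br <- band(n); Bc <- band(m)
  v <- values; v[!valid] <- 0; v[!is.finite(v)] <- 0
  num <- Br %*% v %*% t(Bc)
  if (!renormalize) return(num)
  w <- matrix(0, n, m); w[valid] <- 1
  den <- Br %*% w %*% t(Bc)
  out <- num / den
  out[!valid] <- NA_real_
  out
}
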
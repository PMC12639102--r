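# Density-based clustering (DBSCAN semantics) for samples drawn from a
# discrete spatial map. Samples drawn from a binned distribution all fall on
# bin centers, so the epsilon-neighborhood count of every sample reduces to a
# weighted sum of per-bin sample counts over bins within epsilon. This makes
# the clustering exact and cheap on the 45 x 45 grid, independent of the
# number of samples.

#' DBSCAN over grid-binned sample counts
#'
#' @param counts matrix of sample counts per bin (rows index x bins)
#' @param eps_bins neighborhood radius in bin units (Euclidean, on bin
#'   indices)
#' @param min_pts minimum number of neighbors (including the point itself)
#'   for a sample to be a core point
#' @return integer matrix of cluster labels per bin (0 = noise / empty); all
#'   samples in one bin share a label
#' @export
dbscan_grid <- function(counts, eps_bins, min_pts) {
  n <- nrow(counts); m <- ncol(counts)
  occ <- which(counts > 0, arr.ind = TRUE)
  labels <- matrix(0L, n, m)
  if (nrow(occ) == 0L) return(labels)
  # neighbor offsets within eps (bin-index metric)
  r <- floor(eps_bins)
  off <- expand.grid(dx = -r:r, dy = -r:r)
  off <- off[off$dx^2 + off$dy^2 <= eps_bins^2 + 1e-9, ]
  # neighborhood count per occupied bin
  nb_count <- integer(nrow(occ))
  occ_idx <- matrix(0L, n, m)
  occ_idx[occ] <- seq_len(nrow(occ))
  for (i in seq_len(nrow(occ))) {
    xs <- occ[i, 1] + off$dx; ys <- occ[i, 2] + off$dy
    ok <- xs >= 1 & xs <= n & ys >= 1 & ys <= m
    nb_count[i] <- sum(counts[cbind(xs[ok], ys[ok])])
  }
  core <- nb_count >= min_pts
  # clusters: connected components of core bins under the eps adjacency
  cl <- 0L
  for (i in seq_len(nrow(occ))) {
    if (!core[i] || labels[occ[i, 1], occ[i, 2]] != 0L) next
    cl <- cl + 1L
    queue <- i
    labels[occ[i, 1], occ[i, 2]] <- cl
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      xs <- occ[j, 1] + off$dx; ys <- occ[j, 2] + off$dy
      ok <- xs >= 1 & xs <= n & ys >= 1 & ys <= m
      for (t in which(ok)) {
        oi <- occ_idx[xs[t], ys[t]]
        if (oi == 0L) next
        if (labels[xs[t], ys[t]] == 0L) {
          labels[xs[t], ys[t]] <- cl
          if (core[oi]) queue <- c(queue, oi)  # border bins join, don't expand
        }
      }
    }
  }
  labels
}
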
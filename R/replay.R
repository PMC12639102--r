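# Ripple/burst-independent replay detection: window validity criteria,
# candidate extraction and merging, spatial dispersion, and the place-cell-ID
# shuffle test. No ripple or population-burst requirement appears anywhere in
# this path.

#' Window validity mask
#'
#' A decoded window is valid when the rat is still (speed < 5 cm/s at the
#' window center), the posterior is compact (m < 10 cm), and the center of
#' mass moves smoothly to the next retained window (delta < 20 cm; the jump
#' gates the earlier window only, and only when the next window itself
#' passes the speed and spread criteria).
#'
#' @param post an `rf_posterior`
#' @param pos a `position_series` (speed interpolated to window centers)
#' @param speed_max,m_max,delta_max the three thresholds
#' @return logical vector, one entry per window
#' @export
validity_mask <- function(post, pos, speed_max = 5, m_max = 10,
                          delta_max = 20) {
  s <- post$summary
  v <- stats::approx(pos$t, pos$speed, s$t, rule = 2)$y
  base <- v < speed_max & s$m < m_max
  nxt <- c(base[-1], FALSE)
  jump_fail <- !is.na(s$delta) & s$delta >= delta_max & nxt
  base & !jump_fail
}

#' Extract candidate events and merge across short gaps
#'
#' Maximal runs of valid windows become candidates; neighboring candidates
#' merge when the temporal gap is at most `time_gap` and the spatial gap
#' between the last COM of the earlier run and the first COM of the later
#' run is at most `space_gap`. Merging proceeds transitively left to right.
#'
#' @param mask logical vector from [validity_mask()]
#' @param post the `rf_posterior` the mask refers to
#' @param time_gap s (default 0.05)
#' @param space_gap cm (default 20)
#' @return list of candidates; each has `start`, `end` (window-center
#'   times), `idx` (window indices), `path` (data.frame t, x, y),
#'   `merged_from`
#' @export
extract_and_merge <- function(mask, post, time_gap = 0.05, space_gap = 20) {
  s <- post$summary
  r <- rle(mask)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (!length(keep)) return(list())
  cands <- lapply(keep, function(q) {
    idx <- starts[q]:ends[q]
    list(start = s$t[idx[1]], end = s$t[idx[length(idx)]], idx = idx,
         merged_from = 1L)
  })
  out <- list(cands[[1]])
  for (i in seq_along(cands)[-1]) {
    prev <- out[[length(out)]]
    cur <- cands[[i]]
    tgap <- cur$start - prev$end
    pi1 <- prev$idx[length(prev$idx)]; ci0 <- cur$idx[1]
    sgap <- sqrt((s$x_cm[pi1] - s$x_cm[ci0])^2 +
                 (s$y_cm[pi1] - s$y_cm[ci0])^2)
    if (tgap <= time_gap + 1e-9 && sgap <= space_gap) {
      prev$end <- cur$end
      prev$idx <- c(prev$idx, cur$idx)
      prev$merged_from <- prev$merged_from + 1L
      out[[length(out)]] <- prev
    } else out[[length(out) + 1L]] <- cur
  }
  lapply(out, function(cd) {
    cd$path <- data.frame(t = s$t[cd$idx], x = s$x_cm[cd$idx],
                          y = s$y_cm[cd$idx])
    cd
  })
}

#' Spatial dispersion of a decoded path
#'
#' Default (`form = "rms"`): D is the root-mean-square distance of the path
#' from its mean location, in cm, directly comparable to the 12 cm
#' acceptance gate. `form = "literal"` computes D^2 as the mean of the
#' unsquared distances instead (D then has sqrt(cm) units).
#'
#' @param x,y path coordinates (cm)
#' @param form dispersion convention
#' @return D (scalar)
#' @export
dispersion <- function(x, y, form = c("rms", "literal")) {
  form <- match.arg(form)
  mx <- mean(x); my <- mean(y)
  d <- sqrt((x - mx)^2 + (y - my)^2)
  if (form == "rms") sqrt(mean(d^2)) else sqrt(mean(d))
}

#' Place-cell-ID shuffle test for a candidate event
#'
#' The event is re-decoded `n` times with the assignment between cells and
#' place fields permuted (a fresh permutation of the session's place cells
#' per shuffle, without replacement), recording the mean posterior spread
#' and mean COM jump of each re-decode. P-values are the fraction of
#' shuffles with a *smaller* value than the actual event, so a genuine
#' replay (more compact and smoother than any shuffled geometry) gets small
#' p-values.
#'
#' @param candidate a candidate from [extract_and_merge()]
#' @param post the `rf_posterior` (provides per-window spike counts)
#' @param decoder the `rf_decoder` used for the original decode
#' @param n number of shuffles (default 100)
#' @param seed RNG seed
#' @param convention spread convention (see [posterior_summaries()])
#' @return list with `p_spread`, `p_jump`, `actual` (mean spread/jump) and
#'   the shuffle distributions
#' @export
cell_id_shuffle_test <- function(candidate, post, decoder, n = 100,
                                 seed = 1, convention = "trace") {
  if (n < 1) stop("need at least one shuffle")
  K <- post$counts[candidate$idx, , drop = FALSE]
  base_pen <- post$tau * colSums(decoder$F)
  summarize <- function(logF) {
    ll <- K %*% logF
    ll <- sweep(ll, 2, base_pen)
    ll <- ll - apply(ll, 1, max)
    P <- exp(ll); P <- P / rowSums(P)
    sm <- posterior_summaries(P, decoder$bx, decoder$by, convention)
    c(spread = mean(sm$m),
      jump = mean(sm$delta[-length(sm$delta)], na.rm = TRUE))
  }
  actual <- summarize(decoder$logF)
  rng <- local_rng(seed)
  shuf <- vapply(seq_len(n), function(s) {
    perm <- sample(nrow(decoder$logF))
    summarize(decoder$logF[perm, , drop = FALSE])
  }, numeric(2))
  restore_rng(rng)
  list(p_spread = mean(shuf["spread", ] < actual["spread"]),
       p_jump = mean(shuf["jump", ] < actual["jump"]),
       actual = actual,
       shuffle_spread = shuf["spread", ], shuffle_jump = shuf["jump", ])
}

#' Detect replay events from a decoded session
#'
#' Applies the validity criteria, extracts and merges candidates, and
#' accepts candidates whose duration exceeds `min_duration`, whose spatial
#' dispersion exceeds `min_dispersion`, and whose place-cell-ID shuffle
#' p-values (spread and jump) are both below `alpha`. Low-dispersion
#' (stationary) events are rejected by the dispersion gate.
#'
#' @param post an `rf_posterior`
#' @param pos a `position_series`
#' @param decoder the `rf_decoder`
#' @param min_duration s (default 0.1, strict)
#' @param min_dispersion cm (default 12)
#' @param n_shuffle ID-shuffle count (default 100)
#' @param alpha shuffle significance level (default 0.05)
#' @param seed RNG seed
#' @param dispersion_form see [dispersion()]
#' @return data.frame of candidate events (one row each) with columns
#'   `start`, `end`, `duration`, `D`, `p_spread`, `p_jump`, `accepted`;
#'   accepted events' paths are attached as attribute `paths` (a list of
#'   data.frames t, x, y)
#' @export
detect_replays <- function(post, pos, decoder, min_duration = 0.1,
                           min_dispersion = 12, n_shuffle = 100,
                           alpha = 0.05, seed = 1,
                           dispersion_form = "rms") {
  mask <- validity_mask(post, pos)
  cands <- extract_and_merge(mask, post)
  if (!length(cands)) {
    out <- data.frame(start = numeric(0), end = numeric(0),
                      duration = numeric(0), D = numeric(0),
                      p_spread = numeric(0), p_jump = numeric(0),
                      accepted = logical(0))
    attr(out, "paths") <- list()
    return(out)
  }
  rows <- vector("list", length(cands))
  paths <- list()
  for (i in seq_along(cands)) {
    cd <- cands[[i]]
    dur <- cd$end - cd$start
    D <- dispersion(cd$path$x, cd$path$y, dispersion_form)
    p_s <- NA_real_; p_j <- NA_real_
    acc <- dur > min_duration && D > min_dispersion
    if (acc) {  # shuffle test only for candidates passing the cheap gates
      sh <- cell_id_shuffle_test(cd, post, decoder, n_shuffle,
                                 seed = substream(seed, "shuffle") + i)
      p_s <- sh$p_spread; p_j <- sh$p_jump
      acc <- p_s < alpha && p_j < alpha
    }
    rows[[i]] <- data.frame(start = cd$start, end = cd$end, duration = dur,
                            D = D, p_spread = p_s, p_jump = p_j,
                            accepted = acc)
    if (acc) paths[[length(paths) + 1L]] <- cd$path
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "paths") <- paths
  out
}
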
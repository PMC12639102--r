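# RNG scoping and seed substreams.
#
# Public functions that consume randomness take an explicit seed and leave
# the caller's RNG state untouched. A single session seed is expanded into
# per-component substreams through a fixed documented mapping so components
# stay reproducible independently of each other.

local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# fixed component offsets; derived seeds stay below 2^31 - 1
.rf_substreams <- c(trajectory = 101L, run_spikes = 202L, replays = 303L,
                    lfp = 404L, zones = 505L, shuffle = 606L,
                    snippets = 707L, centers = 808L, misc = 909L)

#' Derive a per-component seed from a session seed
#' @param seed integer session seed
#' @param component one of the documented substream names
#' @return integer seed
#' @export
substream <- function(seed, component) {
  off <- .rf_substreams[[component]]
  as.integer((as.numeric(seed) * 2654435761 + off * 97) %% 2147483587)
}

# log-sum-exp over rows of a matrix
row_logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}
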
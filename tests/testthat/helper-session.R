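# Shared fixtures, generated in code and cached per test run.

# small synthetic session used across test files
small_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- synthetic_config()
      cfg$duration_s <- 120
      cfg$n_replays <- 8
      cache <<- make_session(42, cfg)
    }
    cache
  }
})

# straight constant-speed replay paths reflecting at the walls, for field
# tests that do not need a full session
straight_paths <- function(n_rep, seed, speed = 400, t_gap = 10,
                           dur_range = c(0.2, 0.6), arena = 90) {
  set.seed(seed)
  refl <- function(v) {
    v <- v %% (2 * arena)
    ifelse(v > arena, 2 * arena - v, v)
  }
  lapply(seq_len(n_rep), function(r) {
    dur <- stats::runif(1, dur_range[1], dur_range[2])
    nstep <- round(dur / 0.005)
    x0 <- stats::runif(1, 5, arena - 5)
    y0 <- stats::runif(1, 5, arena - 5)
    th <- stats::runif(1, 0, 2 * pi)
    d <- speed * 0.005 * (seq_len(nstep) - 1)
    data.frame(t = (r - 1) * t_gap + 0.005 * (seq_len(nstep) - 1),
               x = refl(x0 + cos(th) * d), y = refl(y0 + sin(th) * d))
  })
}

# autocorrelated z-scored signal series covering [0, t_max]
ar_signal <- function(t_max, seed, fs = 200, ar = 0.95) {
  set.seed(seed)
  t <- seq(0, t_max, by = 1 / fs)
  z <- as.numeric(stats::arima.sim(list(ar = ar), length(t)))
  z <- (z - mean(z)) / sd(z)
  structure(data.frame(t = t, z = z), fs = fs, kind = "test",
            mean = 0, sd = 1, class = c("signal_series", "data.frame"))
}

# brute-force Bayesian decoder used as the oracle for decode_window
brute_force_posterior <- function(k, F, tau) {
  L <- ncol(F)
  p <- numeric(L)
  for (j in seq_len(L)) {
    v <- 1
    for (i in seq_along(k)) v <- v * F[i, j]^k[i] * exp(-tau * F[i, j])
    p[j] <- v
  }
  p / sum(p)
}
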
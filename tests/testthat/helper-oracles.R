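# Independent oracles and fixture builders shared across test files.

# Literal, unoptimized transcription of the event-calling rule: nested
# loops, no shared state with the package implementation. The shift frame t
# is called when the filtered values at t..t+persistence all strictly
# exceed the larger of mean(prev 3) + 3 * sd(prev 10) and
# mean(prev 3) + fixed offset.
oracle_detect <- function(trace, cfg) {
  n <- length(trace)
  if (n < cfg$sd_lookback + cfg$persistence + 1) return(integer(0))
  h <- (cfg$median_window - 1) / 2
  f <- numeric(n)
  for (i in 1:n) {
    win <- c()
    for (j in (i - h):(i + h)) if (j >= 1 && j <= n) win <- c(win, trace[j])
    f[i] <- median(win)
  }
  calls <- integer(0)
  t <- 1
  while (t <= n) {
    if (t <= cfg$sd_lookback || t + cfg$persistence > n) {
      t <- t + 1
      next
    }
    m <- 0
    for (j in 1:cfg$mean_lookback) m <- m + f[t - j]
    m <- m / cfg$mean_lookback
    xs <- c()
    for (j in 1:cfg$sd_lookback) xs <- c(xs, f[t - j])
    s <- sd(xs)
    thr_a <- m + cfg$sd_multiplier * s
    thr_b <- m + cfg$fixed_offset
    thr <- if (thr_a > thr_b) thr_a else thr_b
    all_above <- TRUE
    for (j in 0:cfg$persistence) {
      if (!(f[t + j] > thr)) all_above <- FALSE
    }
    if (all_above) {
      calls <- c(calls, t)
      t <- t + cfg$persistence + 1
    } else {
      t <- t + 1
    }
  }
  as.integer(calls)
}

# Random trace mix used for the detector equivalence checks: flat noise,
# single steps and occasional double steps with varied parameters.
random_trace <- function() {
  n <- sample(30:80, 1)
  tr <- rnorm(n, sd = runif(1, 0.05, 0.3))
  if (runif(1) < 0.6) {
    t0 <- sample(12:(n - 7), 1)
    a <- runif(1, 0.2, 20)
    k <- runif(1, 0, 0.15)
    idx <- t0:n
    tr[idx] <- tr[idx] + a * exp(-k * (idx - t0))
  }
  if (runif(1) < 0.2) {
    t0 <- sample(12:(n - 7), 1)
    tr[t0:n] <- tr[t0:n] + runif(1, 0.2, 5)
  }
  tr
}

# Minimal hand-built scene: one list of frames with constant images, for
# measure/mask tests that need exact pixel control.
flat_scene <- function(n = 40, n_frames = 3, sirna = 0, egfp = 0,
                       nuclear = 0, sirna_z2 = 0) {
  fr <- list(z1 = list(sirna = matrix(sirna, n, n),
                       egfp = matrix(egfp, n, n),
                       nuclear = matrix(nuclear, n, n)),
             z2 = list(sirna = matrix(sirna_z2, n, n)))
  structure(list(frames = rep(list(fr), n_frames),
                 frame_index = seq_len(n_frames)),
            class = "scene")
}

disk <- function(n, cx, cy, r) {
  outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, `+`) <= r^2
}
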
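# Shared fixtures and independent oracles, built in code at test time.

# Noise-free, drift-free generator: the deterministic backbone of many tests.
clean_config <- function(seed = 1L, ...) {
  args <- list(drift_rate = 0, drift_walk_sigma = 0, line_noise_amp = 0,
               white_noise_sigma = 0, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(gen_config, args)
}

# Standard calibration session (three repetitions of every class).
make_calibration <- function(config = gen_config(seed = 101L)) {
  sched <- make_schedule(
    c("right", "left", "right_blink", "left_blink", "bite", "normal_blink"),
    repeats = 3, interval = 3
  )
  sess <- synthesize(sched, config)
  list(session = sess,
       cal = calibrate_thresholds(sess$recording, sess$truth))
}

# Brute-force double-loop oracle for the rectified moving average.
rma_oracle <- function(x, n) {
  m <- length(x)
  y <- numeric(m)
  for (t in seq_len(m)) {
    i0 <- max(1L, t - n + 1L)
    s <- 0
    for (i in i0:t) s <- s + abs(x[i])
    y[t] <- s / (t - i0 + 1L)
  }
  y
}

# Analytic squared magnitude response of a bilinear-transform Butterworth
# filter applied forward-backward (prewarped frequencies).
butter_mag2 <- function(f, fc, fs, order = 2, type = c("high", "low")) {
  type <- match.arg(type)
  w <- tan(pi * f / fs)
  wc <- tan(pi * fc / fs)
  h <- if (type == "high") {
    (w / wc)^order / sqrt(1 + (w / wc)^(2 * order))
  } else {
    1 / sqrt(1 + (w / wc)^(2 * order))
  }
  h^2   # two passes
}

# RMS of the central portion of a trace (edges trimmed).
central_rms <- function(x, trim = 0.1) {
  n <- length(x)
  i <- seq.int(floor(n * trim) + 1, ceiling(n * (1 - trim)))
  sqrt(mean(x[i]^2))
}

# Mean power in a window, explicit loop (independent of package vector code).
window_power <- function(x, i0, i1) {
  s <- 0
  for (i in i0:i1) s <- s + x[i]^2
  s / (i1 - i0 + 1L)
}
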
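#' Preprocessing configuration
#'
#' Bundles the filtering and activity-detection parameters shared by the EOG
#' and sEMG processing chains.
#'
#' @param emg_highpass_cutoff sEMG high-pass cutoff in Hz. The default removes
#'   electrode DC offset and 60 Hz power-line interference ahead of burst
#'   detection.
#' @param eog_ac_highpass_cutoff High-pass cutoff (Hz) of the AC EOG path,
#'   which isolates saccade-onset transients from the slowly varying gaze
#'   level.
#' @param eog_dc_lowpass_cutoff Low-pass cutoff (Hz) of the DC EOG path; gaze
#'   position information lives well below 10 Hz.
#' @param filter_order Butterworth order used by both paths (applied
#'   forward-backward, so the effective attenuation is doubled).
#' @param ma_window Rectified moving-average window length in samples
#'   (`n = 50`, i.e. 50 ms at 1 kHz).
#' @param min_active_duration Minimum supra-threshold duration (seconds) for
#'   an interval to count as muscle activity.
#' @return A list of class `preprocess_config`.
#' @examples
#' preprocess_config()
#' @export
preprocess_config <- function(emg_highpass_cutoff = 66.7,
                              eog_ac_highpass_cutoff = 0.5,
                              eog_dc_lowpass_cutoff = 10,
                              filter_order = 2L,
                              ma_window = 50L,
                              min_active_duration = 0.05) {
  assert_scalar_number(emg_highpass_cutoff, "emg_highpass_cutoff", 0, strict = TRUE)
  assert_scalar_number(eog_ac_highpass_cutoff, "eog_ac_highpass_cutoff", 0, strict = TRUE)
  assert_scalar_number(eog_dc_lowpass_cutoff, "eog_dc_lowpass_cutoff", 0, strict = TRUE)
  assert_scalar_number(filter_order, "filter_order", 1)
  assert_scalar_number(ma_window, "ma_window", 1)
  assert_scalar_number(min_active_duration, "min_active_duration", 0)
  structure(
    list(
      emg_highpass_cutoff = emg_highpass_cutoff,
      eog_ac_highpass_cutoff = eog_ac_highpass_cutoff,
      eog_dc_lowpass_cutoff = eog_dc_lowpass_cutoff,
      filter_order = as.integer(filter_order),
      ma_window = as.integer(ma_window),
      min_active_duration = min_active_duration
    ),
    class = "preprocess_config"
  )
}

# Forward-backward IIR filtering with odd (reflection) extension at both
# ends and steady-state initial conditions, which suppresses the edge
# transients of naive filtfilt. The extension length scales with the
# filter's time constant.
filtfilt_refl <- function(flt, x, cutoff, fs) {
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(3 * fs / cutoff)))
  if (pad > 0) {
    left <- 2 * x[1] - x[seq(pad + 1L, 2L)]
    right <- 2 * x[n] - x[seq(n - 1L, n - pad)]
    ext <- c(left, x, right)
  } else {
    ext <- x
  }
  ord <- length(flt$a) - 1L
  dc_gain <- sum(flt$b) / sum(flt$a)
  one_pass <- function(v) {
    as.numeric(signal::filter(flt$b, flt$a, v,
                              init.x = rep(v[1], ord),
                              init.y = rep(v[1] * dc_gain, ord)))
  }
  y <- rev(one_pass(rev(one_pass(ext))))
  if (pad > 0) y <- y[(pad + 1L):(pad + n)]
  y
}

butter_check <- function(cutoff, fs) {
  assert_scalar_number(cutoff, "cutoff", 0, strict = TRUE)
  assert_scalar_number(fs, "fs", 0, strict = TRUE)
  if (cutoff >= fs / 2) {
    stop_invalid_argument(sprintf(
      "`cutoff` (%g Hz) must be below the Nyquist frequency (%g Hz).", cutoff, fs / 2
    ))
  }
}

#' Zero-phase Butterworth high-pass filter
#'
#' Designs a digital Butterworth high-pass filter and applies it
#' forward-backward (zero phase), so onset timing is preserved across the DC
#' and AC signal paths.
#'
#' @param x Numeric signal trace.
#' @param cutoff Cutoff frequency in Hz (must be below Nyquist).
#' @param fs Sampling rate in Hz.
#' @param order Butterworth order (per pass).
#' @return Filtered trace of the same length as `x`.
#' @examples
#' x <- sin(2 * pi * 5 * seq(0, 1, by = 1e-3))
#' y <- highpass(x, 60, fs = 1000)
#' @export
highpass <- function(x, cutoff, fs, order = 2L) {
  butter_check(cutoff, fs)
  if (length(x) == 0) return(numeric(0))
  flt <- signal::butter(order, cutoff / (fs / 2), type = "high")
  filtfilt_refl(flt, x, cutoff, fs)
}

#' Zero-phase Butterworth low-pass filter
#'
#' @inheritParams highpass
#' @return Filtered trace of the same length as `x`.
#' @export
lowpass <- function(x, cutoff, fs, order = 2L) {
  butter_check(cutoff, fs)
  if (length(x) == 0) return(numeric(0))
  flt <- signal::butter(order, cutoff / (fs / 2), type = "low")
  filtfilt_refl(flt, x, cutoff, fs)
}

#' Rectified moving average
#'
#' Causal activity envelope: at each sample the unweighted mean of the
#' absolute values of the previous `n` samples (including the current one).
#' During warm-up (the first `n - 1` samples) the mean is taken over the
#' available prefix, which avoids spurious onset activity from zero padding.
#'
#' @param x Numeric signal trace.
#' @param n Window length in samples (>= 1).
#' @return Envelope trace, same length as `x`.
#' @examples
#' rectified_moving_average(c(-1, 1, -1, 1), n = 2)
#' @export
rectified_moving_average <- function(x, n) {
  assert_scalar_number(n, "n", 1)
  n <- as.integer(n)
  m <- length(x)
  if (m == 0) return(numeric(0))
  cs <- cumsum(abs(x))
  idx <- seq_len(m)
  y <- numeric(m)
  warm <- idx < n
  y[warm] <- cs[warm] / idx[warm]
  if (any(!warm)) {
    full <- idx[!warm]
    lag <- c(0, cs)[full - n + 1L]
    y[!warm] <- (cs[full] - lag) / n
  }
  y
}

#' Detect supra-threshold activity intervals
#'
#' Finds maximal runs where the envelope exceeds `threshold` and keeps those
#' lasting at least `min_duration`. Intervals are half-open in sample index,
#' reported in seconds.
#'
#' @param y Envelope trace (e.g. from [rectified_moving_average()]).
#' @param threshold Activity threshold (signal units, > 0).
#' @param min_duration Minimum duration in seconds.
#' @param fs Sampling rate in Hz.
#' @return A tibble with columns `start`, `end` (seconds); zero rows when no
#'   activity is found.
#' @examples
#' y <- c(rep(0, 100), rep(1, 300), rep(0, 600))
#' detect_active(y, threshold = 0.5, min_duration = 0.05, fs = 1000)
#' @export
detect_active <- function(y, threshold, min_duration, fs) {
  assert_scalar_number(threshold, "threshold", 0, strict = TRUE)
  assert_scalar_number(min_duration, "min_duration", 0)
  assert_scalar_number(fs, "fs", 0, strict = TRUE)
  if (length(y) == 0) return(tibble(start = numeric(0), end = numeric(0)))
  above <- y > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- tibble(
    start = (starts[keep] - 1L) / fs,
    end = ends[keep] / fs
  )
  out[out$end - out$start >= min_duration, ]
}
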
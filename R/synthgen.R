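#' Action labels understood by the generator and recognizer
#'
#' The five command classes (`right`, `left` eye movements; `right_blink`,
#' `left_blink`, `bite` facial sEMG actions), the non-command eye movements
#' (`up`, `down`), the involuntary `normal_blink` the system must reject, and
#' `none` (a silent slot).
#'
#' @return Character vector of valid labels.
#' @export
event_labels <- function() {
  c("right", "left", "up", "down",
    "right_blink", "left_blink", "bite", "normal_blink", "none")
}

command_labels <- function() c("right", "left", "right_blink", "left_blink", "bite")

#' Default event durations by action class
#'
#' Saccadic fixations are held 0.8 s; voluntary blink/bite bursts last 0.3 s;
#' involuntary blinks are brief (0.2 s).
#'
#' @return Named numeric vector of durations in seconds.
#' @export
default_durations <- function() {
  c(right = 0.8, left = 0.8, up = 0.8, down = 0.8,
    right_blink = 0.3, left_blink = 0.3, bite = 0.3,
    normal_blink = 0.2, none = 0.5)
}

#' Synthetic-generator configuration
#'
#' Parameters of the six-channel signal generator. Signal units are arbitrary
#' normalized units (the recording chain amplifies raw potentials ~1000x and
#' no absolute calibration exists); all thresholds downstream are expressed in
#' the same units.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param drift_rate Linear baseline drift slope (units/s) on the DC EOG
#'   channels.
#' @param drift_walk_sigma Gaussian random-walk drift intensity (units per
#'   square-root second), applied independently per DC channel.
#' @param line_noise_amp Amplitude of common-mode 60 Hz power-line
#'   interference.
#' @param white_noise_sigma Standard deviation of white measurement noise per
#'   channel.
#' @param saccade_amplitude_h Per-channel horizontal saccade plateau amplitude;
#'   the derived horizontal trace (CH1 - CH2) swings twice this value.
#' @param saccade_amplitude_v Vertical plateau amplitude; vertical EOG
#'   deflections are weaker and slower than horizontal ones, so the default is
#'   below `saccade_amplitude_h`.
#' @param emg_burst_amp Standard deviation of the band-limited noise carrier
#'   of a voluntary sEMG burst at peak envelope.
#' @param normal_blink_amp_fraction Involuntary-blink sEMG amplitude as a
#'   fraction of the voluntary amplitude, strictly below the calibrated
#'   voluntary threshold.
#' @param tail Quiet padding appended after the last event (seconds).
#' @param seed Integer seed; the same (schedule, config) pair always yields an
#'   identical recording.
#' @return A list of class `gen_config`.
#' @examples
#' gen_config(seed = 1)
#' @export
gen_config <- function(sampling_rate = 1000,
                       drift_rate = 0.02,
                       drift_walk_sigma = 0.01,
                       line_noise_amp = 0.05,
                       white_noise_sigma = 0.03,
                       saccade_amplitude_h = 1.0,
                       saccade_amplitude_v = 0.6,
                       emg_burst_amp = 1.0,
                       normal_blink_amp_fraction = 0.4,
                       tail = 2,
                       seed = 1L) {
  assert_scalar_number(sampling_rate, "sampling_rate", 0, strict = TRUE)
  for (nm in c("drift_walk_sigma", "line_noise_amp", "white_noise_sigma",
               "saccade_amplitude_h", "saccade_amplitude_v", "emg_burst_amp")) {
    assert_scalar_number(get(nm), nm, 0)
  }
  assert_scalar_number(drift_rate, "drift_rate")
  assert_scalar_number(normal_blink_amp_fraction, "normal_blink_amp_fraction", 0)
  assert_scalar_number(tail, "tail", 0)
  assert_scalar_number(seed, "seed")
  structure(
    list(
      sampling_rate = sampling_rate,
      drift_rate = drift_rate,
      drift_walk_sigma = drift_walk_sigma,
      line_noise_amp = line_noise_amp,
      white_noise_sigma = white_noise_sigma,
      saccade_amplitude_h = saccade_amplitude_h,
      saccade_amplitude_v = saccade_amplitude_v,
      emg_burst_amp = emg_burst_amp,
      normal_blink_amp_fraction = normal_blink_amp_fraction,
      tail = tail,
      seed = as.integer(seed)
    ),
    class = "gen_config"
  )
}

#' Per-user variation of a generator configuration
#'
#' Emulates individual differences between users by jittering the saccade and
#' sEMG burst amplitudes by up to +/-15% around the base configuration,
#' deterministically from `user_seed`.
#'
#' @param base A [gen_config()].
#' @param user_seed Integer seed identifying the simulated user.
#' @return A modified `gen_config`.
#' @export
gen_config_user <- function(base = gen_config(), user_seed = 1L) {
  stopifnot(inherits(base, "gen_config"))
  withr::with_seed(as.integer(user_seed), {
    base$saccade_amplitude_h <- base$saccade_amplitude_h * runif(1, 0.85, 1.15)
    base$saccade_amplitude_v <- base$saccade_amplitude_v * runif(1, 0.85, 1.15)
    base$emg_burst_amp <- base$emg_burst_amp * runif(1, 0.85, 1.15)
  })
  base$seed <- derive_seed(base$seed, user_seed)
  base
}

#' Build an action schedule
#'
#' Lays out `repeats` presentations of each label at a fixed inter-action
#' interval, either blocked (all repeats of a label consecutively) or shuffled.
#'
#' @param labels Character vector of action labels (see [event_labels()]).
#' @param repeats Number of presentations per label (>= 1).
#' @param interval Inter-action onset spacing in seconds; must exceed the
#'   longest event duration.
#' @param shuffle Randomize presentation order?
#' @param seed Integer seed controlling the shuffle.
#' @param durations Named duration lookup, seconds per label.
#' @param amplitude_scale Per-event amplitude multiplier.
#' @return A tibble of events: `label`, `onset`, `duration`,
#'   `amplitude_scale`, sorted and non-overlapping.
#' @examples
#' make_schedule(c("right", "left"), repeats = 2, interval = 3)
#' @export
make_schedule <- function(labels, repeats = 1L, interval = 3,
                          shuffle = FALSE, seed = 1L,
                          durations = default_durations(),
                          amplitude_scale = 1) {
  if (length(labels) == 0 || !all(labels %in% event_labels())) {
    stop_invalid_argument("`labels` must be a non-empty subset of event_labels().")
  }
  assert_scalar_number(repeats, "repeats", 1)
  assert_scalar_number(interval, "interval", 0, strict = TRUE)
  assert_scalar_number(amplitude_scale, "amplitude_scale", 0)
  durs <- durations[labels]
  if (anyNA(durs)) stop_invalid_argument("`durations` must cover every label.")
  if (interval <= max(durs)) {
    stop_invalid_argument("`interval` must exceed the maximum event duration.")
  }
  seq_labels <- rep(labels, each = as.integer(repeats))
  if (isTRUE(shuffle)) {
    seq_labels <- withr::with_seed(as.integer(seed), sample(seq_labels))
  }
  tibble(
    label = seq_labels,
    onset = interval * seq_along(seq_labels),
    duration = unname(durations[seq_labels]),
    amplitude_scale = amplitude_scale
  )
}

validate_schedule <- function(schedule) {
  if (nrow(schedule) == 0) return(invisible(schedule))
  req <- c("label", "onset", "duration")
  if (!all(req %in% names(schedule))) {
    stop_invalid_argument("Schedule must have columns label, onset, duration.")
  }
  if (!all(schedule$label %in% event_labels())) {
    stop_invalid_argument("Schedule contains unknown labels.")
  }
  if (any(schedule$onset < 0) || any(schedule$duration <= 0)) {
    abort_oculoemg("Schedule onsets must be >= 0 and durations > 0.", "invalid_schedule")
  }
  if (is.unsorted(schedule$onset)) {
    abort_oculoemg("Schedule events must be sorted by onset.", "invalid_schedule")
  }
  ends <- schedule$onset + schedule$duration
  if (any(utils::head(ends, -1) > utils::tail(schedule$onset, -1))) {
    abort_oculoemg("Schedule events overlap.", "invalid_schedule")
  }
  invisible(schedule)
}

# Linear rise / hold / linear return plateau, vectorized over t.
trapezoid <- function(t, onset, duration, rise, amp) {
  amp * pmax(0, pmin(1, (t - onset) / rise, (onset + duration + rise - t) / rise))
}

# Raised-cosine bump spanning [onset, onset + duration].
cosine_bump <- function(t, onset, duration, amp) {
  u <- (t - onset) / duration
  ifelse(u > 0 & u < 1, amp * sin(pi * u)^2, 0)
}

# Raised-cosine (Tukey) envelope with `taper` seconds on each flank.
burst_envelope <- function(t, onset, duration, taper = 0.05) {
  u <- t - onset
  env <- numeric(length(t))
  inside <- u >= 0 & u <= duration
  env[inside] <- 1
  rise <- u >= 0 & u < taper
  env[rise] <- 0.5 * (1 - cos(pi * u[rise] / taper))
  fall <- u > duration - taper & u <= duration
  env[fall] <- 0.5 * (1 - cos(pi * (duration - u[fall]) / taper))
  env
}

#' Synthesize a six-channel EOG/sEMG recording
#'
#' Renders an action schedule into the six channels the interface device
#' streams: CH1/CH2 carry mixed horizontal and vertical EOG components with
#' opposite horizontal polarity (`CH1 = +h + v`, `CH2 = -h + v`, plus drift
#' and noise), so the channel difference isolates horizontal gaze and the sum
#' isolates vertical gaze. CH3/CH4 are the AC paths: band-passed copies of
#' CH1/CH2 showing transient spikes at saccade onset and offset. CH5/CH6 are
#' the right- and left-side facial sEMG channels: a right blink energizes CH5
#' only, a left blink CH6 only, a bite both; an involuntary `normal_blink`
#' produces a weak bilateral burst (below the voluntary calibration level)
#' together with a small vertical EOG transient.
#'
#' @param schedule Event tibble from [make_schedule()] (sorted,
#'   non-overlapping).
#' @param config A [gen_config()].
#' @return A list of class `synth_session` with elements `recording` (tibble
#'   `t`, `ch1_dc`, ..., `ch6_emg`, with a `sampling_rate` attribute), `truth`
#'   (the ground-truth schedule), and `config`.
#' @examples
#' sess <- synthesize(make_schedule("right"), gen_config(seed = 7))
#' dim(sess$recording)
#' @export
synthesize <- function(schedule, config = gen_config()) {
  stopifnot(inherits(config, "gen_config"))
  validate_schedule(schedule)
  fs <- config$sampling_rate
  total <- if (nrow(schedule) == 0) config$tail else
    max(schedule$onset + schedule$duration) + config$tail
  n <- as.integer(round(total * fs))
  t <- (seq_len(n) - 1L) / fs

  h <- numeric(n); v <- numeric(n)
  burst5 <- numeric(n); burst6 <- numeric(n)

  withr::with_seed(config$seed, {
    for (i in seq_len(nrow(schedule))) {
      lab <- schedule$label[i]
      on <- schedule$onset[i]
      du <- schedule$duration[i]
      sc <- schedule$amplitude_scale[i] %||% 1
      if (lab %in% c("right", "left")) {
        a <- config$saccade_amplitude_h * sc * if (lab == "right") 1 else -1
        h <- h + trapezoid(t, on, du, rise = 0.04, amp = a)
      } else if (lab %in% c("up", "down")) {
        a <- config$saccade_amplitude_v * sc * if (lab == "up") 1 else -1
        v <- v + trapezoid(t, on, du, rise = 0.06, amp = a)
      } else if (lab %in% c("right_blink", "left_blink", "bite")) {
        env <- burst_envelope(t, on, du)
        amp <- config$emg_burst_amp * sc
        if (lab != "left_blink") burst5 <- burst5 + env * rnorm(n, 0, amp)
        if (lab != "right_blink") burst6 <- burst6 + env * rnorm(n, 0, amp)
      } else if (lab == "normal_blink") {
        env <- burst_envelope(t, on, du)
        amp <- config$emg_burst_amp * config$normal_blink_amp_fraction * sc
        burst5 <- burst5 + env * rnorm(n, 0, amp)
        burst6 <- burst6 + env * rnorm(n, 0, amp)
        v <- v + cosine_bump(t, on, du, 0.5 * config$saccade_amplitude_v * sc)
      }
    }

    drift1 <- config$drift_rate * t +
      cumsum(rnorm(n, 0, config$drift_walk_sigma / sqrt(fs)))
    drift2 <- config$drift_rate * t +
      cumsum(rnorm(n, 0, config$drift_walk_sigma / sqrt(fs)))
    line <- if (config$line_noise_amp > 0) {
      config$line_noise_amp * sin(2 * pi * 60 * t + runif(1, 0, 2 * pi))
    } else 0
    wn <- function() if (config$white_noise_sigma > 0)
      rnorm(n, 0, config$white_noise_sigma) else 0

    ch1 <- h + v + drift1 + line + wn()
    ch2 <- -h + v + drift2 + line + wn()
    ch5 <- band_limit_emg(burst5, fs) + line + wn()
    ch6 <- band_limit_emg(burst6, fs) + line + wn()
  })

  # AC paths: the analog chain low-passes then high-passes each EOG channel.
  ch3 <- ac_path(ch1, fs)
  ch4 <- ac_path(ch2, fs)

  recording <- tibble(
    t = t, ch1_dc = ch1, ch2_dc = ch2, ch3_ac = ch3, ch4_ac = ch4,
    ch5_emg = ch5, ch6_emg = ch6
  )
  attr(recording, "sampling_rate") <- fs
  structure(
    list(recording = recording, truth = schedule, config = config),
    class = "synth_session"
  )
}

ac_path <- function(x, fs, pp = preprocess_config()) {
  if (all(x == 0)) return(x)
  highpass(lowpass(x, pp$eog_dc_lowpass_cutoff, fs, pp$filter_order),
           pp$eog_ac_highpass_cutoff, fs, pp$filter_order)
}

band_limit_emg <- function(x, fs, cutoff = 66.7) {
  if (all(x == 0)) return(x)
  highpass(x, cutoff, fs, order = 2L)
}

#' @export
print.synth_session <- function(x, ...) {
  fs <- recording_fs(x$recording)
  cat(sprintf(
    "<synth_session> %d samples @ %g Hz (%.1f s), %d scheduled events\n",
    nrow(x$recording), fs, nrow(x$recording) / fs, nrow(x$truth)
  ))
  if (nrow(x$truth) > 0) {
    tab <- table(x$truth$label)
    cat("  events:", paste(sprintf("%s x%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}
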
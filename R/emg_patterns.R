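#' Per-user calibration thresholds
#'
#' Container for the user-specific detection thresholds: sEMG activity
#' thresholds on the right-side (CH5) and left-side (CH6) channels, and the
#' DC/AC EOG saccade thresholds. All values are in normalized signal units.
#'
#' @param emg_threshold_ch5,emg_threshold_ch6 sEMG envelope thresholds (> 0).
#' @param eog_dc_threshold Threshold on the DC excursion from the front-gaze
#'   reference (> 0).
#' @param eog_ac_threshold Threshold on the AC transient (> 0).
#' @param overlap_window Two per-channel sEMG intervals whose gap or overlap
#'   is within this window (seconds) merge into one bilateral episode.
#' @return A list of class `user_calibration`.
#' @export
user_calibration <- function(emg_threshold_ch5,
                             emg_threshold_ch6,
                             eog_dc_threshold,
                             eog_ac_threshold,
                             overlap_window = 0.05) {
  for (nm in c("emg_threshold_ch5", "emg_threshold_ch6",
               "eog_dc_threshold", "eog_ac_threshold")) {
    assert_scalar_number(get(nm), nm, 0, strict = TRUE)
  }
  assert_scalar_number(overlap_window, "overlap_window", 0)
  structure(
    list(
      emg_threshold_ch5 = emg_threshold_ch5,
      emg_threshold_ch6 = emg_threshold_ch6,
      eog_dc_threshold = eog_dc_threshold,
      eog_ac_threshold = eog_ac_threshold,
      overlap_window = overlap_window
    ),
    class = "user_calibration"
  )
}

#' @export
print.user_calibration <- function(x, ...) {
  cat(sprintf(
    paste0("<user_calibration> sEMG ch5=%.3f ch6=%.3f | ",
           "EOG dc=%.3f ac=%.3f | overlap=%.2fs\n"),
    x$emg_threshold_ch5, x$emg_threshold_ch6,
    x$eog_dc_threshold, x$eog_ac_threshold, x$overlap_window
  ))
  invisible(x)
}

event_window_peak <- function(y, onset, duration, fs, pad = 0.1) {
  n <- length(y)
  i0 <- max(1L, as.integer(floor(onset * fs)) + 1L)
  i1 <- min(n, as.integer(ceiling((onset + duration + pad) * fs)))
  if (i0 > i1) return(NA_real_)
  max(y[i0:i1])
}

#' Calibrate per-user thresholds from a labeled recording
#'
#' Thresholds are empirically determined for each user from a calibration
#' session containing voluntary sEMG actions (right blink, left blink, bite),
#' involuntary normal blinks, and left/right eye movements.
#'
#' Per sEMG channel the threshold is
#' `max(rest_mean + k_sigma * rest_sd, midpoint(normal-blink peak, weakest
#' voluntary peak))`, so it clears the noise floor, rejects every calibration
#' normal blink, and accepts every voluntary action. EOG thresholds are set at
#' 40% of the median per-event DC excursion (and AC transient peak) of the
#' labeled left/right saccades.
#'
#' @param recording Recording tibble (see [synthesize()]).
#' @param truth Ground-truth event tibble (`label`, `onset`, `duration`).
#' @param k_sigma Noise-floor multiplier for the rest-based threshold bound.
#' @param pp A [preprocess_config()].
#' @return A [user_calibration()].
#' @export
calibrate_thresholds <- function(recording, truth, k_sigma = 5,
                                 pp = preprocess_config()) {
  assert_recording(recording)
  fs <- recording_fs(recording)
  need <- c("right_blink", "left_blink", "bite", "normal_blink", "right", "left")
  missing_lab <- setdiff(need, unique(truth$label))
  if (length(missing_lab) > 0) {
    abort_oculoemg(paste0(
      "Calibration recording must contain at least one event of each of: ",
      paste(missing_lab, collapse = ", ")
    ), "insufficient_data")
  }

  y5 <- rectified_moving_average(
    highpass(recording$ch5_emg, pp$emg_highpass_cutoff, fs, pp$filter_order),
    pp$ma_window)
  y6 <- rectified_moving_average(
    highpass(recording$ch6_emg, pp$emg_highpass_cutoff, fs, pp$filter_order),
    pp$ma_window)

  # Rest mask: samples at least 0.3 s away from any scheduled event.
  n <- nrow(recording)
  rest <- rep(TRUE, n)
  for (i in seq_len(nrow(truth))) {
    i0 <- max(1L, as.integer(floor((truth$onset[i] - 0.3) * fs)))
    i1 <- min(n, as.integer(ceiling((truth$onset[i] + truth$duration[i] + 0.3) * fs)))
    if (i0 <= i1) rest[i0:i1] <- FALSE
  }
  if (!any(rest)) {
    abort_oculoemg("Calibration recording has no rest samples.", "insufficient_data")
  }

  peaks <- function(y, labels) {
    ev <- truth[truth$label %in% labels, ]
    vapply(seq_len(nrow(ev)), function(i) {
      event_window_peak(y, ev$onset[i], ev$duration[i], fs)
    }, numeric(1))
  }

  thr_for <- function(y, voluntary_labels) {
    vol <- peaks(y, voluntary_labels)
    nb <- peaks(y, "normal_blink")
    if (min(vol) <= max(nb)) {
      abort_oculoemg(paste0(
        "Weakest voluntary sEMG peak (", signif(min(vol), 3),
        ") does not exceed the strongest normal-blink peak (",
        signif(max(nb), 3), "); thresholds cannot separate the classes."
      ), "calibration_infeasible")
    }
    max(mean(y[rest]) + k_sigma * sd(y[rest]), (max(nb) + min(vol)) / 2)
  }

  thr5 <- thr_for(y5, c("right_blink", "bite"))
  thr6 <- thr_for(y6, c("left_blink", "bite"))

  # EOG thresholds from labeled left/right saccades on the derived traces.
  lp1 <- lowpass(recording$ch1_dc, pp$eog_dc_lowpass_cutoff, fs, pp$filter_order)
  lp2 <- lowpass(recording$ch2_dc, pp$eog_dc_lowpass_cutoff, fs, pp$filter_order)
  h_dc <- lp1 - lp2
  h_ac <- recording$ch3_ac - recording$ch4_ac
  sacc <- truth[truth$label %in% c("right", "left"), ]
  exc <- vapply(seq_len(nrow(sacc)), function(i) {
    on <- sacc$onset[i]; du <- sacc$duration[i]
    base_i <- max(1L, as.integer(floor((on - 0.5) * fs))):max(1L, as.integer(floor(on * fs)))
    ref <- median(h_dc[base_i])
    event_window_peak(abs(h_dc - ref), on, du, fs)
  }, numeric(1))
  acp <- vapply(seq_len(nrow(sacc)), function(i) {
    event_window_peak(abs(h_ac), sacc$onset[i], sacc$duration[i], fs)
  }, numeric(1))

  user_calibration(
    emg_threshold_ch5 = thr5,
    emg_threshold_ch6 = thr6,
    eog_dc_threshold = 0.4 * median(exc),
    eog_ac_threshold = 0.4 * median(acp)
  )
}

#' Classify an sEMG activity episode by its channel pattern
#'
#' Right-side channel only -> `right_blink`; left-side channel only ->
#' `left_blink`; both channels -> `bite` (a bite or strong bilateral blink is
#' scored as the single `bite` class). Vectorized over episodes.
#'
#' @param ch5_active,ch6_active Logical: was the channel active during the
#'   episode?
#' @return Character vector of labels.
#' @examples
#' classify_episode(TRUE, FALSE)  # "right_blink"
#' @export
classify_episode <- function(ch5_active, ch6_active) {
  if (length(ch5_active) != length(ch6_active)) {
    stop_invalid_argument("`ch5_active` and `ch6_active` must have equal length.")
  }
  if (any(!ch5_active & !ch6_active)) {
    abort_oculoemg("An episode must have at least one active channel.",
                   "invalid_episode")
  }
  dplyr::case_when(
    ch5_active & ch6_active ~ "bite",
    ch5_active ~ "right_blink",
    TRUE ~ "left_blink"
  )
}

#' Extract and classify sEMG activity episodes
#'
#' Applies the sEMG chain (high-pass filter, rectified moving average,
#' thresholding) per channel, then merges per-channel activity intervals
#' whose overlap or gap is within `cal$overlap_window` into single episodes
#' with joint channel flags. Sub-threshold activity -- in particular the weak
#' bilateral burst of an involuntary blink -- produces no episode.
#'
#' @param ch5,ch6 Raw sEMG traces (right and left side), equal length.
#' @param cal A [user_calibration()].
#' @param pp A [preprocess_config()].
#' @param fs Sampling rate in Hz.
#' @return Tibble of episodes: `start`, `end`, `ch5_active`, `ch6_active`,
#'   `peak_ch5`, `peak_ch6`, `label`.
#' @export
extract_episodes <- function(ch5, ch6, cal, pp = preprocess_config(), fs = 1000) {
  stopifnot(inherits(cal, "user_calibration"))
  if (length(ch5) != length(ch6)) {
    stop_invalid_argument("`ch5` and `ch6` must have equal length.")
  }
  y5 <- rectified_moving_average(
    highpass(ch5, pp$emg_highpass_cutoff, fs, pp$filter_order), pp$ma_window)
  y6 <- rectified_moving_average(
    highpass(ch6, pp$emg_highpass_cutoff, fs, pp$filter_order), pp$ma_window)
  i5 <- detect_active(y5, cal$emg_threshold_ch5, pp$min_active_duration, fs)
  i6 <- detect_active(y6, cal$emg_threshold_ch6, pp$min_active_duration, fs)
  iv <- bind_rows(mutate(i5, channel = 5L), mutate(i6, channel = 6L))
  if (nrow(iv) == 0) {
    return(tibble(start = numeric(0), end = numeric(0),
                  ch5_active = logical(0), ch6_active = logical(0),
                  peak_ch5 = numeric(0), peak_ch6 = numeric(0),
                  label = character(0)))
  }
  iv <- arrange(iv, .data$start)
  ep_id <- integer(nrow(iv))
  cur <- 1L
  cur_end <- iv$end[1]
  ep_id[1] <- 1L
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] - cur_end <= cal$overlap_window) {
      ep_id[i] <- cur
      cur_end <- max(cur_end, iv$end[i])
    } else {
      cur <- cur + 1L
      ep_id[i] <- cur
      cur_end <- iv$end[i]
    }
  }
  iv$episode <- ep_id
  eps <- iv |>
    group_by(.data$episode) |>
    summarise(
      start = min(.data$start),
      end = max(.data$end),
      ch5_active = any(.data$channel == 5L),
      ch6_active = any(.data$channel == 6L),
      .groups = "drop"
    )
  eps$peak_ch5 <- vapply(seq_len(nrow(eps)), function(i) {
    event_window_peak(y5, eps$start[i], eps$end[i] - eps$start[i], fs, pad = 0)
  }, numeric(1))
  eps$peak_ch6 <- vapply(seq_len(nrow(eps)), function(i) {
    event_window_peak(y6, eps$start[i], eps$end[i] - eps$start[i], fs, pad = 0)
  }, numeric(1))
  eps$label <- classify_episode(eps$ch5_active, eps$ch6_active)
  select(eps, -"episode")
}
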
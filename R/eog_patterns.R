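#' Derive vertical and horizontal EOG components
#'
#' With the cross-channel electrode montage both channels record a mixture of
#' horizontal and vertical gaze components with opposite horizontal polarity,
#' so the channel sum isolates the vertical component and the difference the
#' horizontal component: `v = ch1 + ch2`, `h = ch1 - ch2`.
#'
#' @param ch1,ch2 DC (or AC) EOG traces of equal length.
#' @return Tibble with columns `v` and `h`.
#' @seealso [recover_channels()] for the exact inverse.
#' @examples
#' derive_vh(c(1, 2), c(-1, -2))  # pure horizontal
#' @export
derive_vh <- function(ch1, ch2) {
  if (length(ch1) != length(ch2)) {
    stop_invalid_argument("`ch1` and `ch2` must have equal length.")
  }
  tibble(v = ch1 + ch2, h = ch1 - ch2)
}

#' Recover channel traces from derived components
#'
#' Exact algebraic inverse of [derive_vh()]: `ch1 = (v + h) / 2`,
#' `ch2 = (v - h) / 2`.
#'
#' @param v,h Vertical and horizontal component traces of equal length.
#' @return Tibble with columns `ch1` and `ch2`.
#' @export
recover_channels <- function(v, h) {
  if (length(v) != length(h)) {
    stop_invalid_argument("`v` and `h` must have equal length.")
  }
  tibble(ch1 = (v + h) / 2, ch2 = (v - h) / 2)
}

#' Front-gaze baseline state
#'
#' Bookkeeping for the DC reference levels taken when the eyes look straight
#' ahead, renewed whenever the AC element has been quiet and the sEMG
#' inactive for at least `quiet_window` seconds.
#'
#' @param h_ref,v_ref Current DC reference levels (signal units).
#' @param last_renewal Time of the last renewal (seconds, >= 0).
#' @param quiet_window Required quiet duration before renewal (seconds).
#' @return A list of class `baseline_state`.
#' @export
baseline_state <- function(h_ref = 0, v_ref = 0, last_renewal = 0,
                           quiet_window = 0.5) {
  assert_scalar_number(last_renewal, "last_renewal", 0)
  assert_scalar_number(quiet_window, "quiet_window", 0, strict = TRUE)
  structure(
    list(h_ref = h_ref, v_ref = v_ref, last_renewal = last_renewal,
         quiet_window = quiet_window, quiet_since = NA_real_,
         refs_valid = FALSE),
    class = "baseline_state"
  )
}

#' Advance the baseline-renewal rule by one sample
#'
#' When the AC element of the EOG has not changed (the eyes are not moving)
#' and the sEMG is not active, and both conditions have held for at least
#' `quiet_window`, the DC reference values are re-initialized to the current
#' DC samples (the eyes are taken to be looking at the front). Otherwise the
#' state is unchanged apart from quiet-run bookkeeping.
#'
#' @param state A [baseline_state()].
#' @param h_dc,v_dc Current DC sample values of the derived horizontal and
#'   vertical traces.
#' @param ac_quiet Logical: is the AC element within its baseline band?
#' @param emg_inactive Logical: is the sEMG inactive?
#' @param t Current time in seconds.
#' @return The updated `baseline_state`.
#' @export
renew_baseline <- function(state, h_dc, v_dc, ac_quiet, emg_inactive, t) {
  stopifnot(inherits(state, "baseline_state"))
  if (!isTRUE(ac_quiet) || !isTRUE(emg_inactive)) {
    state$quiet_since <- NA_real_
    return(state)
  }
  if (is.na(state$quiet_since)) state$quiet_since <- t
  if (t - state$quiet_since >= state$quiet_window) {
    state$h_ref <- h_dc
    state$v_ref <- v_dc
    state$last_renewal <- t
    state$refs_valid <- TRUE
  }
  state
}

#' Vertical gate: classify a deflection as horizontal or vertical
#'
#' Compares the changing range of the channel-sum (vertical) and
#' channel-difference (horizontal) components. When the horizontal range is
#' strictly larger the deflection is treated as a horizontal saccade;
#' otherwise (including ties) as vertical, because vertical EOG deflections
#' resemble blink artifacts and are never emitted as commands.
#'
#' @param delta_v,delta_h Changing ranges of the vertical and horizontal
#'   components (signal units). Vectorized.
#' @return Character vector, `"horizontal"` or `"vertical"`.
#' @examples
#' vertical_gate(0.1, 0.8)  # "horizontal"
#' @export
vertical_gate <- function(delta_v, delta_h) {
  ifelse(abs(delta_h) > abs(delta_v), "horizontal", "vertical")
}

#' Saccade state-machine options
#'
#' @param ac_band_fraction The AC element counts as "returned to baseline"
#'   when its magnitude is below this fraction of the AC threshold.
#' @param dc_band_fraction Baseline band for the DC element, as a fraction of
#'   the DC threshold.
#' @param refractory Dead time (seconds) after an event completes, to
#'   suppress double-triggering.
#' @param mask_margin Padding (seconds) added around sEMG episodes when
#'   masking EOG processing.
#' @return A list of class `saccade_options`.
#' @export
saccade_options <- function(ac_band_fraction = 0.2,
                            dc_band_fraction = 0.2,
                            refractory = 0.3,
                            mask_margin = 0.1) {
  assert_scalar_number(ac_band_fraction, "ac_band_fraction", 0, strict = TRUE)
  assert_scalar_number(dc_band_fraction, "dc_band_fraction", 0, strict = TRUE)
  assert_scalar_number(refractory, "refractory", 0)
  assert_scalar_number(mask_margin, "mask_margin", 0)
  structure(
    list(ac_band_fraction = ac_band_fraction,
         dc_band_fraction = dc_band_fraction,
         refractory = refractory,
         mask_margin = mask_margin),
    class = "saccade_options"
  )
}

#' Detect saccades with the four-step DC/AC state machine
#'
#' Runs the per-sample recognition procedure on the derived EOG traces:
#' \enumerate{
#'   \item The DC and AC elements simultaneously exceed the direction
#'     threshold: the direction is determined and the event emitted.
#'   \item The DC element stays beyond threshold while the AC element
#'     returns to baseline: the gaze continues off-center.
#'   \item An AC excursion of opposite sign marks the return toward center.
#'   \item Both elements return within their baseline bands; the DC baseline
#'     is updated and a refractory period begins.
#' }
#' Left saccades mirror the signs. Candidate deflections whose vertical range
#' exceeds the horizontal range are labeled `vertical` and emit no command.
#' While the recognizer is idle, the front-gaze reference is continuously
#' renewed after every `quiet_window` of AC/sEMG quiet, which bounds the
#' effect of baseline drift.
#'
#' @param h_dc,h_ac Derived horizontal DC and AC traces.
#' @param v_dc Derived vertical DC trace.
#' @param v_ac Derived vertical AC trace (defaults to zeros when the AC
#'   vertical path is unavailable).
#' @param state A [baseline_state()] carrying initial references and the
#'   quiet window.
#' @param cal A [user_calibration()] providing the DC/AC thresholds.
#' @param fs Sampling rate in Hz.
#' @param options A [saccade_options()].
#' @param emg_active Optional logical mask; samples with sEMG activity are
#'   excluded from EOG processing and force re-initialization of the
#'   references afterwards.
#' @param return_trace Also return the per-sample machine state (for
#'   debugging dumps)?
#' @return A tibble of events (`label` in right/left/vertical, `onset`,
#'   `offset` in seconds, `peak_dc_excursion`), sorted and non-overlapping.
#'   With `return_trace = TRUE`, a list with elements `events`, `trace`
#'   (tibble `t`, `state`; -1 denotes sEMG-masked samples), and `state` (the
#'   final `baseline_state`).
#' @export
detect_saccades <- function(h_dc, h_ac, v_dc, v_ac = NULL,
                            state = baseline_state(), cal,
                            fs = 1000, options = saccade_options(),
                            emg_active = NULL, return_trace = FALSE) {
  stopifnot(inherits(cal, "user_calibration"),
            inherits(state, "baseline_state"),
            inherits(options, "saccade_options"))
  n <- length(h_dc)
  if (is.null(v_ac)) v_ac <- numeric(n)
  if (is.null(emg_active)) emg_active <- logical(n)
  if (length(h_ac) != n || length(v_dc) != n || length(v_ac) != n ||
      length(emg_active) != n) {
    stop_invalid_argument("All traces must have equal length.")
  }
  res <- saccade_fsm_cpp(
    h_dc, h_ac, v_dc, v_ac, emg_active, fs,
    dc_thr = cal$eog_dc_threshold,
    ac_thr = cal$eog_ac_threshold,
    dc_band = options$dc_band_fraction * cal$eog_dc_threshold,
    ac_band = options$ac_band_fraction * cal$eog_ac_threshold,
    quiet_window = state$quiet_window,
    refractory = options$refractory,
    h_ref0 = state$h_ref, v_ref0 = state$v_ref,
    refs_valid0 = isTRUE(state$refs_valid),
    return_trace = return_trace
  )
  events <- tibble(
    label = c("right", "left", "vertical")[res$label + 1L],
    onset = res$onset / fs,
    offset = res$offset / fs,
    peak_dc_excursion = res$peak
  )
  events <- arrange(events, .data$onset)
  if (!return_trace) return(events)
  out_state <- state
  out_state$h_ref <- res$h_ref
  out_state$v_ref <- res$v_ref
  out_state$refs_valid <- res$refs_valid
  if (res$last_renewal >= 0) out_state$last_renewal <- res$last_renewal / fs
  list(
    events = events,
    trace = tibble(t = (seq_len(n) - 1L) / fs, state = res$trace),
    state = out_state
  )
}
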
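#' Run the integrated dual-modality recognizer
#'
#' The full recognition flow: sEMG episodes are detected and classified
#' first and take priority -- samples inside an episode (plus a small margin)
#' are masked from EOG processing, and after each episode the DC references
#' are re-initialized before any further EOG decision. Outside episodes the
#' four-step saccade state machine runs with continuous front-gaze renewal.
#' The result is the merged, time-sorted stream of the five command classes;
#' `vertical` saccade candidates are detected internally but never emitted as
#' commands.
#'
#' @param recording Recording tibble (`t`, `ch1_dc`, ..., `ch6_emg`).
#' @param cal A [user_calibration()].
#' @param pp A [preprocess_config()].
#' @param options A [saccade_options()].
#' @param quiet_window Renewal quiet window in seconds.
#' @return Tibble of classified events: `label` (right, left, right_blink,
#'   left_blink, bite), `onset`, `offset`, `modality` ("EOG"/"sEMG"),
#'   `peak_ch5`, `peak_ch6`, `peak_dc_excursion`.
#' @export
run_recognition <- function(recording, cal, pp = preprocess_config(),
                            options = saccade_options(), quiet_window = 0.5) {
  assert_recording(recording)
  stopifnot(inherits(cal, "user_calibration"))
  fs <- recording_fs(recording)
  n <- nrow(recording)
  if (n / fs < quiet_window) {
    abort_oculoemg(sprintf(
      "Recording (%.3f s) is shorter than the renewal quiet window (%.3f s).",
      n / fs, quiet_window
    ), "insufficient_data")
  }

  episodes <- extract_episodes(recording$ch5_emg, recording$ch6_emg,
                               cal, pp, fs)

  emg_mask <- logical(n)
  for (i in seq_len(nrow(episodes))) {
    i0 <- max(1L, as.integer(floor((episodes$start[i] - options$mask_margin) * fs)))
    i1 <- min(n, as.integer(ceiling((episodes$end[i] + options$mask_margin) * fs)))
    emg_mask[i0:i1] <- TRUE
  }

  lp1 <- lowpass(recording$ch1_dc, pp$eog_dc_lowpass_cutoff, fs, pp$filter_order)
  lp2 <- lowpass(recording$ch2_dc, pp$eog_dc_lowpass_cutoff, fs, pp$filter_order)
  dc <- derive_vh(lp1, lp2)
  ac <- derive_vh(recording$ch3_ac, recording$ch4_ac)

  sacc <- detect_saccades(
    dc$h, ac$h, dc$v, ac$v,
    state = baseline_state(quiet_window = quiet_window),
    cal = cal, fs = fs, options = options, emg_active = emg_mask
  )
  sacc <- sacc[sacc$label %in% c("right", "left"), ]

  eog_events <- tibble(
    label = sacc$label, onset = sacc$onset, offset = sacc$offset,
    modality = rep("EOG", nrow(sacc)),
    peak_ch5 = NA_real_, peak_ch6 = NA_real_,
    peak_dc_excursion = sacc$peak_dc_excursion
  )
  emg_events <- tibble(
    label = episodes$label, onset = episodes$start, offset = episodes$end,
    modality = rep("sEMG", nrow(episodes)),
    peak_ch5 = episodes$peak_ch5, peak_ch6 = episodes$peak_ch6,
    peak_dc_excursion = NA_real_
  )
  arrange(bind_rows(eog_events, emg_events), .data$onset)
}

#' Evaluate classified events against ground truth
#'
#' Each truth event is matched to the nearest prediction whose onset lies
#' within `match_window` seconds (greedy one-to-one matching, processing
#' truth events earliest-first, nearest prediction wins, earlier prediction
#' on ties). Outcomes follow the experimental definitions: a matching label
#' is `correct`; a non-matching label is a `miss` (wrong response); no
#' prediction in the window is a `reject` (no reaction). `normal_blink`
#' truth events expect *no* prediction: absence of a match is scored
#' `correct` (the involuntary blink was properly ignored) and a match is
#' scored `miss` (rejection failure). Predictions left unmatched are
#' reported as spurious in the `"spurious"` attribute and excluded from the
#' per-stimulus rates.
#'
#' @param events Classified-event tibble from [run_recognition()].
#' @param truth Ground-truth tibble (`label`, `onset`).
#' @param match_window Matching half-window in seconds (default half the 3 s
#'   inter-action interval).
#' @return Tibble with one row per truth event: `truth_label`, `onset`,
#'   `predicted_label` (NA when none), `predicted_onset`, `outcome`.
#' @export
evaluate_events <- function(events, truth, match_window = 1.5) {
  if (nrow(truth) == 0) {
    stop_invalid_argument("`truth` must contain at least one event.")
  }
  truth <- arrange(truth, .data$onset)
  used <- rep(FALSE, nrow(events))
  pred_label <- rep(NA_character_, nrow(truth))
  pred_onset <- rep(NA_real_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    if (nrow(events) == 0) break
    d <- abs(events$onset - truth$onset[i])
    cand <- which(!used & d <= match_window)
    if (length(cand) == 0) next
    best <- cand[order(d[cand], events$onset[cand])][1]
    used[best] <- TRUE
    pred_label[i] <- events$label[best]
    pred_onset[i] <- events$onset[best]
  }
  outcome <- ifelse(
    truth$label == "normal_blink",
    ifelse(is.na(pred_label), "correct", "miss"),
    ifelse(is.na(pred_label), "reject",
           ifelse(pred_label == truth$label, "correct", "miss"))
  )
  out <- tibble(
    truth_label = truth$label,
    onset = truth$onset,
    predicted_label = pred_label,
    predicted_onset = pred_onset,
    outcome = outcome
  )
  attr(out, "spurious") <- if (nrow(events)) events[!used, ] else events
  out
}

#' Performance-evaluation score on the 5-point rule
#'
#' `(5 * correct + 2 * reject + 0 * miss) / (correct + reject + miss)`:
#' a correct response earns 5 points, a rejection (no reaction) 2 points and
#' a miss (wrong response) 0 points.
#'
#' @param correct,reject,miss Non-negative trial counts, not all zero.
#' @return Score in \[0, 5\].
#' @examples
#' pe_score(9, 0, 0)  # 5
#' pe_score(0, 9, 0)  # 2
#' @export
pe_score <- function(correct, reject, miss) {
  if (any(c(correct, reject, miss) < 0)) {
    stop_invalid_argument("Counts must be non-negative.")
  }
  total <- correct + reject + miss
  if (any(total == 0)) {
    stop_invalid_argument("At least one count must be positive.")
  }
  (5 * correct + 2 * reject) / total
}

#' Summarize trial outcomes
#'
#' Per-pattern and pooled counts, rates and 5-point performance scores.
#' Pooled rates are computed over all trials (total counts), not as a mean of
#' per-pattern percentages.
#'
#' @param outcomes Outcome tibble from [evaluate_events()] (rows from several
#'   runs may be concatenated).
#' @return An object of class `recognition_summary` with elements
#'   `per_pattern` (tibble: pattern, trials, correct, reject, miss, the
#'   corresponding percentage rates and `pe`) and `overall` (one-row tibble:
#'   trials, accuracy, reject_rate, miss_rate, mean_pe). [tidy()] returns the
#'   per-pattern table, [glance()] the overall row.
#' @export
summarize_recognition <- function(outcomes) {
  if (nrow(outcomes) == 0) {
    stop_invalid_argument("`outcomes` must cover at least one trial.")
  }
  per <- outcomes |>
    group_by(pattern = .data$truth_label) |>
    summarise(
      trials = n(),
      correct = sum(.data$outcome == "correct"),
      reject = sum(.data$outcome == "reject"),
      miss = sum(.data$outcome == "miss"),
      .groups = "drop"
    ) |>
    mutate(
      correct_rate = 100 * .data$correct / .data$trials,
      reject_rate = 100 * .data$reject / .data$trials,
      miss_rate = 100 * .data$miss / .data$trials,
      pe = pe_score(.data$correct, .data$reject, .data$miss)
    )
  tot <- list(
    trials = sum(per$trials),
    correct = sum(per$correct),
    reject = sum(per$reject),
    miss = sum(per$miss)
  )
  overall <- tibble(
    trials = tot$trials,
    accuracy = 100 * tot$correct / tot$trials,
    reject_rate = 100 * tot$reject / tot$trials,
    miss_rate = 100 * tot$miss / tot$trials,
    mean_pe = pe_score(tot$correct, tot$reject, tot$miss)
  )
  structure(list(per_pattern = per, overall = overall),
            class = "recognition_summary")
}

#' @export
print.recognition_summary <- function(x, ...) {
  cat("Recognition summary\n")
  per <- x$per_pattern
  for (i in seq_len(nrow(per))) {
    cat(sprintf(
      "  %-12s %3d trials: %5.1f%% correct, %5.1f%% reject, %5.1f%% miss (PE %.2f)\n",
      per$pattern[i], per$trials[i],
      round_half_up(per$correct_rate[i], 1),
      round_half_up(per$reject_rate[i], 1),
      round_half_up(per$miss_rate[i], 1),
      per$pe[i]
    ))
  }
  ov <- x$overall
  cat(sprintf(
    "  overall      %3d trials: %5.1f%% correct, %5.1f%% reject, %5.1f%% miss (PE %.2f)\n",
    ov$trials, round_half_up(ov$accuracy, 1),
    round_half_up(ov$reject_rate, 1), round_half_up(ov$miss_rate, 1),
    ov$mean_pe
  ))
  invisible(x)
}

#' @rdname summarize_recognition
#' @param x A `recognition_summary`.
#' @param ... Unused.
#' @export
tidy.recognition_summary <- function(x, ...) x$per_pattern

#' @rdname summarize_recognition
#' @export
glance.recognition_summary <- function(x, ...) x$overall
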
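test_that("sEMG activity takes priority and masks concurrent EOG excursions", {
  fix <- make_calibration(gen_config(seed = 301))
  cal <- fix$cal

  sess <- synthesize(make_schedule("bite", repeats = 1, interval = 3),
                     gen_config(seed = 41))
  rec <- sess$recording
  # inject a DC gaze excursion exactly concurrent with the bite burst
  step <- ifelse(rec$t >= 3 & rec$t <= 3.3, 1.2, 0)
  rec$ch1_dc <- rec$ch1_dc + step
  rec$ch2_dc <- rec$ch2_dc - step
  attr(rec, "sampling_rate") <- 1000

  ev <- run_recognition(rec, cal)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$label, "bite")
  expect_equal(ev$modality, "sEMG")
})

test_that("pure sub-threshold noise produces no events", {
  cal <- make_calibration(gen_config(seed = 301))$cal
  sess <- synthesize(make_schedule("none", repeats = 1, interval = 5),
                     gen_config(seed = 43))
  ev <- run_recognition(sess$recording, cal)
  expect_equal(nrow(ev), 0)
})

test_that("too-short recordings raise an insufficient-data error", {
  cal <- make_calibration(gen_config(seed = 301))$cal
  sess <- synthesize(make_schedule("none", repeats = 1, interval = 5),
                     gen_config(seed = 43))
  short <- sess$recording[1:300, ]
  attr(short, "sampling_rate") <- 1000
  expect_error(run_recognition(short, cal),
               class = "oculoemg_insufficient_data")
})

test_that("trial matching implements correct / reject / miss semantics", {
  truth <- tibble::tibble(label = "right", onset = 3.0)
  pred <- function(label, onset) {
    tibble::tibble(label = label, onset = onset, offset = onset + 0.5,
                   modality = "EOG")
  }
  expect_equal(evaluate_events(pred("right", 3.2), truth)$outcome, "correct")
  expect_equal(evaluate_events(pred("right", 3.2)[0, ], truth)$outcome, "reject")
  expect_equal(evaluate_events(pred("left", 3.2), truth)$outcome, "miss")
  # outside the window -> reject, and the prediction becomes spurious
  out <- evaluate_events(pred("right", 5.0), truth, match_window = 1.5)
  expect_equal(out$outcome, "reject")
  expect_equal(nrow(attr(out, "spurious")), 1)

  # normal blinks: no reaction is correct, a reaction is a rejection failure
  blink_truth <- tibble::tibble(label = "normal_blink", onset = 3.0)
  expect_equal(evaluate_events(pred("right", 3.2)[0, ], blink_truth)$outcome,
               "correct")
  expect_equal(evaluate_events(pred("bite", 3.1), blink_truth)$outcome, "miss")

  # greedy one-to-one: each prediction matches at most one truth event
  two_truth <- tibble::tibble(label = c("right", "right"), onset = c(3, 6))
  one_pred <- pred("right", 4.4)
  out2 <- evaluate_events(one_pred, two_truth)
  expect_equal(out2$outcome, c("correct", "reject"))
})

test_that("the 5-point performance score follows the scoring rule", {
  expect_equal(pe_score(9, 0, 0), 5)
  expect_equal(pe_score(0, 9, 0), 2)
  expect_equal(pe_score(0, 0, 9), 0)
  # published right-direction counts: the formula gives 346/72
  expect_equal(pe_score(68, 3, 1), (5 * 68 + 2 * 3) / 72)
  expect_equal(round(pe_score(68, 3, 1), 2), 4.81)
  expect_error(pe_score(0, 0, 0), class = "oculoemg_invalid_argument")
})

test_that("summaries pool counts over trials and preserve rate identities", {
  tabs <- published_tables()
  four <- tabs$pattern_recognition[
    tabs$pattern_recognition$pattern %in%
      c("right", "left", "right_blink", "left_blink"), ]
  s <- summarize_recognition(counts_to_outcomes(four))
  expect_equal(s$overall$trials, 288)
  expect_equal(round_half_up(s$overall$accuracy, 1), 95.1)
  expect_equal(round_half_up(s$overall$reject_rate, 1), 1.4)
  expect_equal(round_half_up(s$overall$miss_rate, 1), 3.5)
  expect_equal(s$overall$accuracy + s$overall$reject_rate + s$overall$miss_rate,
               100, tolerance = 1e-9)

  bite <- tabs$pattern_recognition[tabs$pattern_recognition$pattern == "bite", ]
  sb <- summarize_recognition(counts_to_outcomes(bite))
  expect_equal(round_half_up(sb$overall$accuracy, 0), 67)
  expect_equal(round_half_up(sb$overall$reject_rate, 0), 33)

  all_correct <- tibble::tibble(
    truth_label = rep("right", 10), onset = NA_real_,
    predicted_label = "right", predicted_onset = NA_real_, outcome = "correct"
  )
  sc <- summarize_recognition(all_correct)
  expect_equal(sc$overall$accuracy, 100)
  expect_equal(sc$overall$mean_pe, 5)

  expect_equal(tidy(s), s$per_pattern)
  expect_equal(glance(s), s$overall)
})

test_that("a noise-free protocol run is recognized perfectly end to end", {
  cal_sess <- synthesize(
    make_schedule(c("right", "left", "right_blink", "left_blink", "bite",
                    "normal_blink"), repeats = 3, interval = 3),
    clean_config(seed = 61, white_noise_sigma = 0.01)
  )
  cal <- calibrate_thresholds(cal_sess$recording, cal_sess$truth)
  sess <- synthesize(
    make_schedule(c("right", "left", "right_blink", "left_blink"),
                  repeats = 3, interval = 3, shuffle = TRUE, seed = 8),
    clean_config(seed = 62)
  )
  out <- evaluate_events(run_recognition(sess$recording, cal), sess$truth)
  expect_true(all(out$outcome == "correct"))
})
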
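test_that("calibrated thresholds separate normal blinks from voluntary actions", {
  fix <- make_calibration(gen_config(seed = 101))
  cal <- fix$cal
  sess <- fix$session
  fs <- recording_fs(sess$recording)
  pp <- preprocess_config()

  y5 <- rectified_moving_average(
    highpass(sess$recording$ch5_emg, pp$emg_highpass_cutoff, fs), pp$ma_window)
  peak_in <- function(y, ev) {
    vapply(seq_len(nrow(ev)), function(i) {
      i0 <- as.integer(ev$onset[i] * fs)
      max(y[i0:(i0 + as.integer((ev$duration[i] + 0.1) * fs))])
    }, numeric(1))
  }
  tr <- sess$truth
  vol5 <- peak_in(y5, tr[tr$label %in% c("right_blink", "bite"), ])
  nb5 <- peak_in(y5, tr[tr$label == "normal_blink", ])

  # threshold sits strictly between the normal-blink and voluntary peaks
  expect_gt(cal$emg_threshold_ch5, max(nb5))
  expect_lt(cal$emg_threshold_ch5, min(vol5))
  expect_gt(cal$emg_threshold_ch6, 0)

  # identical input -> identical calibration
  cal2 <- calibrate_thresholds(sess$recording, sess$truth)
  expect_identical(cal, cal2)
})

test_that("calibration fails when normal blinks rival voluntary actions", {
  cfg <- gen_config(seed = 11, normal_blink_amp_fraction = 1.5)
  sched <- make_schedule(
    c("right", "left", "right_blink", "left_blink", "bite", "normal_blink"),
    repeats = 2, interval = 3
  )
  sess <- synthesize(sched, cfg)
  expect_error(calibrate_thresholds(sess$recording, sess$truth),
               class = "oculoemg_calibration_infeasible")
})

test_that("episodes classify by channel pattern and partition the label space", {
  expect_equal(classify_episode(TRUE, FALSE), "right_blink")
  expect_equal(classify_episode(FALSE, TRUE), "left_blink")
  expect_equal(classify_episode(TRUE, TRUE), "bite")
  expect_error(classify_episode(FALSE, FALSE), class = "oculoemg_invalid_episode")
  # vectorized: all combinations map to exactly one of the three labels
  out <- classify_episode(c(TRUE, FALSE, TRUE), c(FALSE, TRUE, TRUE))
  expect_equal(out, c("right_blink", "left_blink", "bite"))
})

test_that("episode extraction finds voluntary bursts and ignores normal blinks", {
  fix <- make_calibration(gen_config(seed = 55))
  cal <- fix$cal

  one_event <- function(label, seed) {
    sess <- synthesize(make_schedule(label, repeats = 1, interval = 3),
                       gen_config(seed = seed))
    extract_episodes(sess$recording$ch5_emg, sess$recording$ch6_emg,
                     cal, fs = recording_fs(sess$recording))
  }

  eps <- one_event("right_blink", 21)
  expect_equal(nrow(eps), 1)
  expect_true(eps$ch5_active && !eps$ch6_active)
  expect_equal(eps$label, "right_blink")
  expect_lt(abs(eps$start - 3), 0.15)

  expect_equal(nrow(one_event("normal_blink", 22)), 0)

  # two voluntary blinks 1 s apart stay distinct episodes
  sched <- tibble::tibble(label = c("left_blink", "left_blink"),
                          onset = c(3, 4), duration = 0.3, amplitude_scale = 1)
  sess <- synthesize(sched, gen_config(seed = 23))
  eps2 <- extract_episodes(sess$recording$ch5_emg, sess$recording$ch6_emg,
                           cal, fs = 1000)
  expect_equal(nrow(eps2), 2)
  expect_equal(eps2$label, c("left_blink", "left_blink"))
})

test_that("episode count is stable under weak added noise", {
  fix <- make_calibration(gen_config(seed = 77))
  cal <- fix$cal
  sess <- synthesize(make_schedule(c("right_blink", "bite"), repeats = 1,
                                   interval = 3),
                     gen_config(seed = 31))
  base <- extract_episodes(sess$recording$ch5_emg, sess$recording$ch6_emg,
                           cal, fs = 1000)
  sigma <- min(cal$emg_threshold_ch5, cal$emg_threshold_ch6) / 10
  for (s in 1:20) {
    set.seed(s)
    n <- nrow(sess$recording)
    eps <- extract_episodes(sess$recording$ch5_emg + rnorm(n, 0, sigma),
                            sess$recording$ch6_emg + rnorm(n, 0, sigma),
                            cal, fs = 1000)
    expect_equal(nrow(eps), nrow(base))
  }
})
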
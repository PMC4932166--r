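test_that("schedules follow the presentation protocol", {
  sched <- make_schedule(
    c("right", "left", "right_blink", "left_blink", "bite"),
    repeats = 9, interval = 3
  )
  expect_equal(nrow(sched), 45)
  expect_equal(sched$onset, 3 * (1:45))

  single <- make_schedule("right", repeats = 1, interval = 3)
  expect_equal(nrow(single), 1)
  expect_equal(single$onset, 3)

  expect_error(make_schedule("right", interval = -1),
               class = "oculoemg_invalid_argument")
  expect_error(make_schedule("right", interval = 0.5),  # below event duration
               class = "oculoemg_invalid_argument")
})

test_that("schedule shuffling is deterministic in the seed", {
  a <- make_schedule(c("right", "left"), repeats = 5, shuffle = TRUE, seed = 4)
  b <- make_schedule(c("right", "left"), repeats = 5, shuffle = TRUE, seed = 4)
  c <- make_schedule(c("right", "left"), repeats = 5, shuffle = TRUE, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$label, c$label))
})

test_that("noise-free synthesis obeys the cross-channel mixing identities", {
  sched <- make_schedule(c("right", "up"), repeats = 1, interval = 3)
  sess <- synthesize(sched, clean_config())
  rec <- sess$recording
  fs <- recording_fs(rec)
  t <- rec$t

  # reconstruct the generator's plateau traces independently
  h_true <- ifelse(t >= 3 & t < 3.04, (t - 3) / 0.04,
            ifelse(t >= 3.04 & t <= 3.8, 1,
            ifelse(t > 3.8 & t < 3.84, (3.84 - t) / 0.04, 0)))
  h_derived <- (rec$ch1_dc - rec$ch2_dc) / 2
  expect_equal(h_derived, h_true, tolerance = 1e-12)

  # the up event appears only in the sum
  v_derived <- (rec$ch1_dc + rec$ch2_dc) / 2
  expect_gt(max(v_derived[t > 6 & t < 6.8]), 0.5)
  expect_lt(max(abs(v_derived[t < 5.9])), 1e-12)

  # right saccade: positive plateau in h, paired AC transients on CH3
  expect_gt(max(rec$ch3_ac[t > 2.9 & t < 3.3]), 0.1)   # onset, positive
  expect_lt(min(rec$ch3_ac[t > 3.7 & t < 4.1]), -0.1)  # offset, negative
})

test_that("empty schedules with zero noise produce silent channels", {
  sched <- make_schedule("right", repeats = 1)[0, ]
  sess <- synthesize(sched, clean_config())
  for (ch in c("ch1_dc", "ch2_dc", "ch3_ac", "ch4_ac", "ch5_emg", "ch6_emg")) {
    expect_equal(max(abs(sess$recording[[ch]])), 0)
  }
})

test_that("a bite energizes both sEMG channels well above rest", {
  sess <- synthesize(make_schedule("bite", repeats = 1, interval = 3),
                     gen_config(seed = 5))
  rec <- sess$recording
  fs <- recording_fs(rec)
  for (ch in c("ch5_emg", "ch6_emg")) {
    p_in <- window_power(rec[[ch]], as.integer(3.0 * fs), as.integer(3.3 * fs))
    p_out <- window_power(rec[[ch]], as.integer(1.0 * fs), as.integer(2.5 * fs))
    expect_gt(p_in, 5 * p_out)
  }
})

test_that("one-sided blinks energize only their own channel", {
  sess <- synthesize(make_schedule("right_blink", repeats = 1, interval = 3),
                     clean_config(seed = 6))
  rec <- sess$recording
  fs <- recording_fs(rec)
  p5 <- window_power(rec$ch5_emg, as.integer(3.0 * fs), as.integer(3.3 * fs))
  p6 <- window_power(rec$ch6_emg, as.integer(3.0 * fs), as.integer(3.3 * fs))
  expect_gt(p5, 100 * max(p6, 1e-12))
})

test_that("synthesis is deterministic given the seed and rejects overlap", {
  sched <- make_schedule(c("right", "bite"), repeats = 2, interval = 3)
  a <- synthesize(sched, gen_config(seed = 9))
  b <- synthesize(sched, gen_config(seed = 9))
  expect_identical(a$recording, b$recording)

  overlapping <- tibble::tibble(
    label = c("right", "left"), onset = c(3, 3.5),
    duration = c(0.8, 0.8), amplitude_scale = 1
  )
  expect_error(synthesize(overlapping, gen_config()),
               class = "oculoemg_invalid_schedule")
})

test_that("per-user variation perturbs amplitudes deterministically", {
  u1 <- gen_config_user(gen_config(), 5)
  u1b <- gen_config_user(gen_config(), 5)
  u2 <- gen_config_user(gen_config(), 6)
  expect_identical(u1, u1b)
  expect_false(u1$saccade_amplitude_h == u2$saccade_amplitude_h)
  expect_lt(abs(u1$saccade_amplitude_h - 1), 0.15 + 1e-9)
})
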
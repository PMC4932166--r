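test_that("component derivation and channel recovery are exact inverses", {
  expect_equal(derive_vh(c(2, 3), c(-2, -3)),
               tibble::tibble(v = c(0, 0), h = c(4, 6)))
  expect_equal(derive_vh(c(1.5, 1.5), c(1.5, 1.5))$v, c(3, 3))
  expect_equal(derive_vh(c(1.5, 1.5), c(1.5, 1.5))$h, c(0, 0))

  set.seed(2)
  ch1 <- rnorm(500); ch2 <- rnorm(500)
  d <- derive_vh(ch1, ch2)
  r <- recover_channels(d$v, d$h)
  expect_equal(r$ch1, ch1, tolerance = 1e-12)
  expect_equal(r$ch2, ch2, tolerance = 1e-12)
  expect_error(derive_vh(1:3, 1:2), class = "oculoemg_invalid_argument")
})

test_that("baseline renewal updates references only after sustained quiet", {
  st <- baseline_state(quiet_window = 0.5)
  # quiet from t=0; at t=0.6 the drifted DC level becomes the reference
  for (t in seq(0, 0.6, by = 0.1)) {
    st <- renew_baseline(st, h_dc = 0.3, v_dc = 0.1, ac_quiet = TRUE,
                         emg_inactive = TRUE, t = t)
  }
  expect_equal(st$h_ref, 0.3)
  expect_equal(st$v_ref, 0.1)
  expect_equal(st$last_renewal, 0.6)

  # AC activity blocks renewal entirely
  st2 <- baseline_state(quiet_window = 0.5)
  for (t in seq(0, 1, by = 0.1)) {
    st2 <- renew_baseline(st2, 0.3, 0.1, ac_quiet = FALSE,
                          emg_inactive = TRUE, t = t)
  }
  expect_equal(st2$h_ref, 0)
  expect_false(st2$refs_valid)

  # after sEMG activity ends, references re-initialize one quiet window later
  st3 <- baseline_state(quiet_window = 0.5)
  times <- seq(0, 2, by = 0.1)
  for (t in times) {
    st3 <- renew_baseline(st3, 0.5, 0, ac_quiet = TRUE,
                          emg_inactive = t >= 1.0, t = t)
  }
  expect_equal(st3$last_renewal, 2.0)
  expect_equal(st3$h_ref, 0.5)
  st4 <- baseline_state(quiet_window = 0.5)
  for (t in times[times <= 1.4]) {
    st4 <- renew_baseline(st4, 0.5, 0, ac_quiet = TRUE,
                          emg_inactive = t >= 1.0, t = t)
  }
  expect_false(st4$refs_valid)  # only 0.4 s of quiet since the episode ended
})

test_that("the vertical gate routes deflections by dominant component", {
  expect_equal(vertical_gate(0.1, 0.8), "horizontal")
  expect_equal(vertical_gate(0.8, 0.1), "vertical")
  expect_equal(vertical_gate(0.5, 0.5), "vertical")  # declared tie-break
  expect_equal(vertical_gate(c(0.1, 0.9), c(0.8, 0.2)),
               c("horizontal", "vertical"))
})

detect_from_session <- function(sess, cal) {
  rec <- sess$recording
  fs <- recording_fs(rec)
  pp <- preprocess_config()
  lp1 <- lowpass(rec$ch1_dc, pp$eog_dc_lowpass_cutoff, fs)
  lp2 <- lowpass(rec$ch2_dc, pp$eog_dc_lowpass_cutoff, fs)
  dc <- derive_vh(lp1, lp2)
  ac <- derive_vh(rec$ch3_ac, rec$ch4_ac)
  detect_saccades(dc$h, ac$h, dc$v, ac$v, cal = cal, fs = fs)
}

test_that("single saccades are detected with the correct label and timing", {
  cal <- make_calibration(gen_config(seed = 201))$cal
  for (lab in c("right", "left")) {
    sess <- synthesize(make_schedule(lab, repeats = 1, interval = 3),
                       clean_config(seed = 7))
    ev <- detect_from_session(sess, cal)
    ev <- ev[ev$label != "vertical", ]
    expect_equal(nrow(ev), 1)
    expect_equal(ev$label, lab)
    expect_lt(abs(ev$onset - 3), 0.1)
  }
})

test_that("noise-free saccades classify perfectly across amplitudes and directions", {
  cal <- make_calibration(gen_config(seed = 201))$cal
  for (lab in c("right", "left")) {
    for (amp in c(0.8, 1.0, 1.2, 1.5, 2.0)) {
      sched <- make_schedule(lab, repeats = 1, interval = 3,
                             amplitude_scale = amp)
      sess <- synthesize(sched, clean_config(seed = 3))
      ev <- detect_from_session(sess, cal)
      ev <- ev[ev$label != "vertical", ]
      expect_equal(ev$label, lab)
    }
  }
})

test_that("flat or drift-only input with renewal yields no events", {
  cal <- make_calibration(gen_config(seed = 201))$cal
  flat <- synthesize(make_schedule("right")[0, ], clean_config())
  expect_equal(nrow(detect_from_session(flat, cal)), 0)

  # 30 s of linear drift (0.02 units/s) plus mild noise, no saccades
  for (s in 1:20) {
    cfg <- gen_config(seed = s, drift_rate = 0.02)
    sched <- make_schedule("none", repeats = 1, interval = 29)
    sess <- synthesize(sched, cfg)
    ev <- detect_from_session(sess, cal)
    expect_equal(nrow(ev[ev$label != "vertical", ]), 0)
  }
})

test_that("detected events are time-sorted and non-overlapping", {
  cal <- make_calibration(gen_config(seed = 201))$cal
  sess <- synthesize(make_schedule(c("right", "left"), repeats = 3,
                                   interval = 3, shuffle = TRUE, seed = 2),
                     gen_config(seed = 12))
  ev <- detect_from_session(sess, cal)
  expect_gt(nrow(ev), 0)
  expect_true(!is.unsorted(ev$onset))
  expect_true(all(ev$onset < ev$offset))
  if (nrow(ev) > 1) expect_true(all(ev$onset[-1] >= ev$offset[-nrow(ev)]))
})

test_that("the state trace is dumpable and spans the recording", {
  cal <- make_calibration(gen_config(seed = 201))$cal
  sess <- synthesize(make_schedule("right"), clean_config(seed = 1))
  rec <- sess$recording
  pp <- preprocess_config()
  dc <- derive_vh(lowpass(rec$ch1_dc, 10, 1000), lowpass(rec$ch2_dc, 10, 1000))
  ac <- derive_vh(rec$ch3_ac, rec$ch4_ac)
  res <- detect_saccades(dc$h, ac$h, dc$v, ac$v, cal = cal, fs = 1000,
                         return_trace = TRUE)
  expect_equal(nrow(res$trace), nrow(rec))
  expect_true(any(res$trace$state > 0))
  expect_true(res$state$refs_valid)
})
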
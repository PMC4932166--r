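# Seeded end-to-end experiment drivers reproducing the pattern-recognition
# protocol: actions presented at 3 s intervals, nine repetitions per class,
# eight participants, plus a separate involuntary-blink rejection test.

calibration_schedule <- function(seed) {
  make_schedule(
    c("right", "left", "right_blink", "left_blink", "bite", "normal_blink"),
    repeats = 3, interval = 3, shuffle = FALSE, seed = seed
  )
}

#' Simulate and calibrate one user session
#'
#' Generates a per-user calibration recording (three repetitions of each of
#' the five voluntary classes and the involuntary blink at 3 s intervals),
#' calibrates thresholds from it, then generates a labeled test recording for
#' the requested classes and runs the full recognizer.
#'
#' @param labels Command classes presented in the test recording.
#' @param repeats Presentations per class.
#' @param base_config Base [gen_config()] (the study conditions).
#' @param user_seed Seed selecting the simulated user (amplitude
#'   idiosyncrasies).
#' @param session_seed Seed for schedules and noise realizations.
#' @param pp A [preprocess_config()].
#' @return List with `outcomes` (from [evaluate_events()]), `events`,
#'   `truth`, and `cal`.
#' @export
simulate_user_session <- function(labels = command_labels()[1:4],
                                  repeats = 9,
                                  base_config = gen_config(),
                                  user_seed = 1L,
                                  session_seed = 1L,
                                  pp = preprocess_config()) {
  cfg <- gen_config_user(base_config, user_seed)
  cal_cfg <- cfg
  cal_cfg$seed <- derive_seed(session_seed, user_seed, 1L)
  cal_sess <- synthesize(calibration_schedule(cal_cfg$seed), cal_cfg)
  cal <- calibrate_thresholds(cal_sess$recording, cal_sess$truth, pp = pp)

  test_cfg <- cfg
  test_cfg$seed <- derive_seed(session_seed, user_seed, 2L)
  sched <- make_schedule(labels, repeats = repeats, interval = 3,
                         shuffle = TRUE, seed = derive_seed(session_seed, user_seed, 3L))
  sess <- synthesize(sched, test_cfg)
  events <- run_recognition(sess$recording, cal, pp = pp)
  outcomes <- evaluate_events(events, sess$truth)
  list(outcomes = outcomes, events = events, truth = sess$truth, cal = cal)
}

#' Multi-user, multi-seed pattern-recognition experiment
#'
#' Runs the four-command protocol (right, left, right blink, left blink; nine
#' presentations each at 3 s intervals) for `n_users` simulated users and
#' `n_seeds` independent noise realizations, and pools correct/reject/miss
#' counts over all trials.
#'
#' @param base_seed Master seed; all per-user and per-seed randomness derives
#'   from it.
#' @param n_seeds Number of independent replicate seeds.
#' @param n_users Number of simulated users.
#' @param repeats Presentations per class per user.
#' @param labels Command classes presented.
#' @param base_config Base [gen_config()].
#' @return List with `summary` (a [summarize_recognition()] object over all
#'   pooled outcomes), `accuracy` (pooled %), `n_trials`, and `per_seed`
#'   (tibble of per-seed accuracies).
#' @export
run_pattern_experiment <- function(base_seed = 1L, n_seeds = 20, n_users = 8,
                                   repeats = 9,
                                   labels = command_labels()[1:4],
                                   base_config = gen_config()) {
  all_outcomes <- vector("list", n_seeds * n_users)
  per_seed <- numeric(n_seeds)
  k <- 0L
  for (s in seq_len(n_seeds)) {
    seed_outcomes <- vector("list", n_users)
    for (u in seq_len(n_users)) {
      res <- simulate_user_session(
        labels = labels, repeats = repeats, base_config = base_config,
        user_seed = derive_seed(base_seed, s, u),
        session_seed = derive_seed(base_seed, s, u, 99L)
      )
      k <- k + 1L
      all_outcomes[[k]] <- res$outcomes
      seed_outcomes[[u]] <- res$outcomes
    }
    so <- bind_rows(seed_outcomes)
    per_seed[s] <- 100 * mean(so$outcome == "correct")
  }
  pooled <- bind_rows(all_outcomes)
  summ <- summarize_recognition(pooled)
  list(
    summary = summ,
    accuracy = summ$overall$accuracy,
    n_trials = nrow(pooled),
    per_seed = tibble(seed = seq_len(n_seeds), accuracy = per_seed)
  )
}

#' Involuntary-blink rejection experiment
#'
#' Presents involuntary (normal) blinks at the default amplitude fraction to
#' calibrated users and measures the percentage that produce no command
#' output from the full recognizer.
#'
#' @inheritParams run_pattern_experiment
#' @param blinks_per_user Normal blinks presented per user per seed.
#' @return List with `rejection_rate` (% of blinks with no command),
#'   `n_blinks`, and the pooled `outcomes`.
#' @export
run_blink_rejection_experiment <- function(base_seed = 1L, n_seeds = 10,
                                           n_users = 8, blinks_per_user = 3,
                                           base_config = gen_config()) {
  all_outcomes <- vector("list", n_seeds * n_users)
  k <- 0L
  for (s in seq_len(n_seeds)) {
    for (u in seq_len(n_users)) {
      cfg <- gen_config_user(base_config, derive_seed(base_seed, s, u, 7L))
      cal_cfg <- cfg
      cal_cfg$seed <- derive_seed(base_seed, s, u, 8L)
      cal_sess <- synthesize(calibration_schedule(cal_cfg$seed), cal_cfg)
      cal <- calibrate_thresholds(cal_sess$recording, cal_sess$truth)

      blink_cfg <- cfg
      blink_cfg$seed <- derive_seed(base_seed, s, u, 9L)
      sched <- make_schedule("normal_blink", repeats = blinks_per_user,
                             interval = 3)
      sess <- synthesize(sched, blink_cfg)
      events <- run_recognition(sess$recording, cal)
      k <- k + 1L
      all_outcomes[[k]] <- evaluate_events(events, sess$truth)
    }
  }
  pooled <- bind_rows(all_outcomes)
  list(
    rejection_rate = 100 * mean(pooled$outcome == "correct"),
    n_blinks = nrow(pooled),
    outcomes = pooled
  )
}
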
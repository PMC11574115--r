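test_that("parse_session is a strict, lossless inverse of write_session", {
  trials <- lapply(1:22, function(i) make_trial(index = i, is_practice = i <= 2))
  s <- make_session(trials = trials)
  expect_s3_class(s, "pat_session")
  expect_equal(nrow(s$trials), 22)

  # round trip write -> parse is identity on content
  f <- tempfile(fileext = ".json")
  write_session(s, f)
  s2 <- parse_session(f)
  expect_equal(s2$trials, s$trials)
  expect_equal(s2$baseline_beats_ms, s$baseline_beats_ms)
  expect_equal(s2$participant_id, s$participant_id)

  # missing required keys are named
  expect_error(parse_session('{"participant_id":"x","task":"pat","baseline_beats_ms":[0,800,1600]}'),
               "`trials`")
  bad_trial <- make_trial()
  bad_trial$selected_delay_ms <- NULL
  expect_error(parse_session(make_session_json(list(bad_trial))),
               "`selected_delay_ms`")
  expect_error(parse_session(make_session_json(list(), task = "other")),
               "screener")
  expect_error(
    parse_session(make_session_json(list(make_trial()),
                                    baseline_beats_ms = c(0, 800, 700))),
    "strictly increasing"
  )
})

test_that("practice trials are removed by flag, with positional fallback", {
  trials <- lapply(1:22, function(i) make_trial(index = i, is_practice = i <= 2))
  s <- make_session(trials = trials)
  expect_equal(nrow(remove_practice(s)$trials), 20)

  # flags absent: first two dropped positionally, with a message
  unflagged <- lapply(1:22, function(i) make_trial(index = i))
  s_un <- make_session(trials = unflagged)
  expect_message(out <- remove_practice(s_un), "positionally")
  expect_equal(out$trials$index, 3:22)

  # degenerate sessions
  s_empty <- make_session(trials = list())
  expect_equal(nrow(remove_practice(s_empty)$trials), 0)
  all_practice <- lapply(1:4, function(i) make_trial(index = i, is_practice = TRUE))
  expect_equal(nrow(remove_practice(make_session(trials = all_practice))$trials), 0)
})

test_that("validity filters remove disengaged and untouched-dial trials", {
  trials <- lapply(1:20, function(i) make_trial(index = i))
  trials[[2]]$hr_samples <- rep(75, 4)   # boundary: 4 samples -> removed
  trials[[5]]$hr_samples <- numeric(0)
  trials[[9]]$hr_samples <- rep(75, 3)
  trials[[12]]$delay_trajectory <- numeric(0)
  s <- make_session(trials = trials)
  out <- filter_valid_trials(s)
  expect_equal(out$report$n_valid, 16)
  expect_equal(out$report$n_removed_few_samples, 3)
  expect_equal(out$report$n_removed_zero_delays, 1)
  expect_equal(out$report$n_trials_in,
               out$report$n_valid + out$report$n_removed_few_samples +
                 out$report$n_removed_zero_delays)

  # exactly 5 heart-rate samples is retained
  five <- make_session(trials = list(make_trial(hr_samples = rep(75, 5))))
  expect_equal(filter_valid_trials(five)$report$n_valid, 1)

  # all-valid input is the identity
  clean <- make_session(n_trials = 20L)
  expect_equal(filter_valid_trials(clean)$session$trials, clean$trials)

  # a single-entry trajectory equal to the recorded default dial position
  # counts as unchanged
  s_def <- make_session(
    trials = list(make_trial(delay_trajectory = 150),
                  make_trial(index = 2L, delay_trajectory = 180)),
    meta = list(default_delay_ms = 150)
  )
  rep_def <- filter_valid_trials(s_def)$report
  expect_equal(rep_def$n_removed_zero_delays, 1)
  expect_equal(rep_def$n_valid, 1)
})

test_that("minimum-trial rule excludes at 16 and truncates to the first 17", {
  s16 <- make_session(n_trials = 16L)
  out16 <- enforce_min_and_truncate(s16)
  expect_true(out16$excluded)
  expect_match(out16$reason, "16 valid")

  s17 <- make_session(n_trials = 17L)
  out17 <- enforce_min_and_truncate(s17)
  expect_false(out17$excluded)
  expect_equal(nrow(out17$session$trials), 17)

  s20 <- make_session(n_trials = 20L)
  out20 <- enforce_min_and_truncate(s20)
  expect_equal(out20$session$trials$index, 1:17)
})

test_that("engagement metrics are means over retained trials", {
  trials <- lapply(1:17, function(i) {
    make_trial(index = i, duration_s = 20,
               delay_trajectory = seq(0, 90, by = 10))
  })
  s <- make_session(trials = trials)
  e <- engagement(s)
  expect_equal(e$mean_time_per_trial_s, 20)
  expect_equal(e$mean_dial_turns, 10)
  expect_equal(e$n_valid_trials, 17)

  # mixed durations: arithmetic mean, hand-computed
  durs <- c(10, 20, 40)
  s2 <- make_session(trials = lapply(1:3, function(i) {
    make_trial(index = i, duration_s = durs[i])
  }))
  expect_equal(engagement(s2)$mean_time_per_trial_s, mean(durs))
})

test_that("the screener gate excludes strictly below the cutoff", {
  expect_equal(screener_gate(0.41), "excluded")
  expect_equal(screener_gate(0.42), "retained")
  expect_equal(screener_gate(1.0), "retained")
  expect_equal(screener_gate(c(0, 0.419999, 0.42, 0.7)),
               c("excluded", "excluded", "retained", "retained"))
  expect_error(screener_gate(1.2), "\\[0, 1\\]")
  expect_error(screener_gate(-0.1), "\\[0, 1\\]")
})

test_that("the QC cascade reconciles counts and removes exactly the injected trials", {
  cfg <- simulation_config(n_participants = 12, p_invalid_trial = 0.25,
                           seed = 55)
  cohort <- simulate_cohort(cfg)
  for (s in cohort$sessions) {
    res <- qc_session(s)
    r <- res$report
    expect_equal(r$n_trials_in,
                 r$n_practice_removed + r$n_removed_few_samples +
                   r$n_removed_zero_delays + r$n_valid)
    # 100% precision/recall against the injection labels
    task_trials <- s$trials[!s$trials$is_practice, ]
    expect_equal(r$n_removed_few_samples,
                 sum(task_trials$injected_invalid == "few_samples"))
    expect_equal(r$n_removed_zero_delays,
                 sum(task_trials$injected_invalid == "untouched_dial"))
    expect_equal(r$passed, sum(task_trials$injected_invalid == "none") >= 17)
    if (r$passed) {
      expect_true(all(res$session$trials$injected_invalid == "none"))
      expect_equal(nrow(res$session$trials), 17)
    }
  }
})
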
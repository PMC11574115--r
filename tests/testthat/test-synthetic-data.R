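test_that("simulate_rr_series honours its moments and boundaries", {
  # zero variance: exact spacing, 10 intervals in 8 s at 800 ms
  set.seed(1)
  ts <- simulate_rr_series(800, 0, 8)
  expect_equal(ts, seq(0, 8000, by = 800))
  expect_length(diff(ts), 10)

  # stochastic case: sample mean RR within 3 SE of the configured mean
  set.seed(2)
  ts <- simulate_rr_series(800, 50, 600)
  rr <- diff(ts)
  expect_true(all(rr >= 300))
  expect_true(all(diff(ts) > 0))
  expect_lt(abs(mean(rr) - 800), 3 * 50 / sqrt(length(rr)))

  expect_error(simulate_rr_series(800, 50, 0), "positive")
  expect_error(simulate_rr_series(0, 50, 10), "positive")
})

test_that("response phases follow the participant's generative regime", {
  # extreme concentration pins all angles to the preferred phase
  p_conc <- list(is_interoceptive = TRUE, kappa = 1e6, mu_phase = pi)
  set.seed(3)
  th <- sample_response_phase(p_conc, 200)
  expect_true(all(abs(th - pi) < 0.01))
  expect_true(all(th >= 0 & th < 2 * pi))

  # kappa = 0 yields circular uniformity (Rayleigh test at n = 1e4)
  p_unif <- list(is_interoceptive = FALSE, kappa = 0, mu_phase = 0)
  set.seed(4)
  th_u <- sample_response_phase(p_unif, 1e4)
  expect_gt(rayleigh_p(th_u), 0.001)

  # same seed, same draws
  set.seed(7)
  a <- sample_response_phase(list(is_interoceptive = TRUE, kappa = 3,
                                  mu_phase = 1), 50)
  set.seed(7)
  b <- sample_response_phase(list(is_interoceptive = TRUE, kappa = 3,
                                  mu_phase = 1), 50)
  expect_identical(a, b)
})

test_that("von Mises sampler matches the Bessel-ratio resultant on a kappa grid", {
  set.seed(8)
  for (kappa in c(0.5, 2, 8)) {
    th <- rvonmises(20000, 2, kappa)
    rho <- besselI(kappa, 1) / besselI(kappa, 0)
    expect_lt(abs(mrl_oracle(th) - rho), 0.015)
    # mean direction recovered
    expect_lt(abs(Arg(mean(exp(1i * th))) - 2), 0.05)
  }
})

test_that("phase_to_delay inverts delay_to_phase", {
  expect_equal(phase_to_delay(pi, 800), 400)
  expect_equal(phase_to_delay(0, 800), 0)
  expect_error(phase_to_delay(pi, -5), "positive")
  expect_error(phase_to_delay(7, 800), "2\\*pi")
  set.seed(9)
  theta <- runif(100, 0, 2 * pi - 1e-9)
  rr <- runif(100, 300, 1500)
  back <- delay_to_phase(phase_to_delay(theta, rr), rr)
  expect_true(all(abs(back - theta) < 1e-9))
  expect_true(all(phase_to_delay(theta, rr) >= 0 &
                    phase_to_delay(theta, rr) < rr))
})

test_that("simulated trials carry the canonical fields and injected failure modes", {
  cfg <- simulation_config(seed = 10)
  profile <- list(is_interoceptive = TRUE, kappa = 4, mu_phase = 1,
                  adherent = TRUE)
  set.seed(10)
  tr <- simulate_trial(profile, cfg)
  expect_gte(length(tr$hr_samples), 5)
  expect_gte(length(unique(tr$delay_trajectory)), 1)
  expect_equal(tr$delay_trajectory[length(tr$delay_trajectory)],
               tr$selected_delay_ms)
  expect_true(tr$selected_delay_ms >= 0 &&
                tr$selected_delay_ms < tr$rr_reference_ms)
  expect_true(tr$confidence %in% 0:9)
  expect_gt(tr$duration_s, 0)

  tr_few <- simulate_trial(profile, cfg, invalid_mode = "few_samples")
  expect_lte(length(tr_few$hr_samples), 4)
  tr_dial <- simulate_trial(profile, cfg, invalid_mode = "untouched_dial")
  expect_length(tr_dial$delay_trajectory, 0)
})

test_that("cohorts are deterministic, labelled, and hit the configured mixture", {
  cfg <- simulation_config(n_participants = 40, seed = 123)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(
    jsonlite::serializeJSON(c1$truth),
    jsonlite::serializeJSON(c2$truth)
  )
  # serialized sessions byte-identical under the same config
  f1 <- tempfile(fileext = ".json")
  f2 <- tempfile(fileext = ".json")
  write_session(c1$sessions[[5]], f1)
  write_session(c2$sessions[[5]], f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_equal(nrow(c1$truth), 40)
  expect_length(c1$sessions, 80) # screener + pat per participant
  expect_true(all(c1$truth$kappa[!c1$truth$is_interoceptive] == 0))
  expect_true(all(c1$truth$kappa[c1$truth$is_interoceptive] >= 1))
  # proportion interoceptive within binomial error of the target
  phat <- mean(c1$truth$is_interoceptive)
  p_target <- cfg$prop_interoceptive * (1 - cfg$p_nonadherent)
  expect_lt(abs(phat - p_target), 3 * sqrt(p_target * (1 - p_target) / 40))

  # empty cohort: empty outputs, no error
  c0 <- simulate_cohort(simulation_config(n_participants = 0))
  expect_length(c0$sessions, 0)
  expect_equal(nrow(c0$truth), 0)
})

test_that("downstream consistency tracks the generative concentration", {
  # all interoceptive at very high kappa: every score clears the screener
  # cutoff by a wide margin
  cfg_hi <- simulation_config(n_participants = 12, prop_interoceptive = 1,
                              kappa_range = c(25, 30), p_invalid_trial = 0,
                              p_nonadherent = 0, seed = 31)
  co <- simulate_cohort(cfg_hi)
  pat <- co$sessions[purrr::map_chr(co$sessions, "task") == "pat"]
  scores <- purrr::map_dbl(pat, function(s) {
    session_consistency(qc_session(s)$session)$value
  })
  expect_true(all(scores > 0.42))

  # none interoceptive: scores centred near the uniform-phase expectation
  cfg_lo <- simulation_config(n_participants = 40, prop_interoceptive = 0,
                              p_invalid_trial = 0, p_nonadherent = 0,
                              seed = 32)
  co_lo <- simulate_cohort(cfg_lo)
  pat_lo <- co_lo$sessions[purrr::map_chr(co_lo$sessions, "task") == "pat"]
  scores_lo <- purrr::map_dbl(pat_lo, function(s) {
    session_consistency(qc_session(s)$session)$value
  })
  expect_lt(abs(mean(scores_lo) - sqrt(pi / 68)),
            3 * sd(scores_lo) / sqrt(length(scores_lo)))

  # expected consistency increases with kappa
  set.seed(33)
  mean_r_at <- function(kappa) {
    mean(replicate(500, mrl_oracle(rvonmises(17, 0, kappa))))
  }
  grid <- c(0.5, 1, 2, 4, 8)
  means <- vapply(grid, mean_r_at, numeric(1))
  expect_true(all(diff(means) > 0))
})
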
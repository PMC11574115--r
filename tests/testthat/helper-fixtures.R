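# Builders for canonical-schema fixtures, constructed in code at test time.

make_trial <- function(index = 1L, is_practice = FALSE,
                       n_hr = 20L, hr_samples = NULL,
                       delay_trajectory = c(100, 250, 400),
                       selected_delay_ms = 400,
                       rr_reference_ms = 800,
                       duration_s = 20, confidence = 5L,
                       injected_invalid = "none") {
  list(
    index = index, is_practice = is_practice,
    hr_samples = if (is.null(hr_samples)) rep(75, n_hr) else hr_samples,
    delay_trajectory = delay_trajectory,
    selected_delay_ms = selected_delay_ms,
    rr_reference_ms = rr_reference_ms,
    duration_s = duration_s, confidence = confidence,
    injected_invalid = injected_invalid
  )
}

# A session as written by the simulator / parsed from JSON: `trials` is a
# list of trial lists here; the JSON round trip through write/parse gives
# the tibble form.
make_session_json <- function(trials, participant_id = "T001", task = "pat",
                              baseline_beats_ms = seq(0, 120000, by = 800),
                              meta = list()) {
  jsonlite::toJSON(
    list(participant_id = participant_id, task = task,
         baseline_beats_ms = baseline_beats_ms, trials = trials,
         meta = meta),
    auto_unbox = TRUE, digits = NA, null = "null"
  )
}

make_session <- function(trials = NULL, n_trials = 19L, delays = NULL, ...) {
  if (is.null(trials)) {
    if (is.null(delays)) delays <- rep(400, n_trials)
    trials <- lapply(seq_len(n_trials), function(i) {
      make_trial(index = i, selected_delay_ms = delays[i])
    })
  }
  parse_session(make_session_json(trials, ...))
}

# Independent oracle for the mean resultant length: explicit cos/sin sums,
# deliberately a separate code path from the implementation.
mrl_oracle <- function(angles) {
  n <- length(angles)
  C <- 0
  S <- 0
  for (a in angles) {
    C <- C + cos(a)
    S <- S + sin(a)
  }
  sqrt((C / n)^2 + (S / n)^2)
}

# Rayleigh test of circular uniformity (Z = n * R^2, with the standard
# finite-sample p approximation); used to check uniform phase generation.
rayleigh_p <- function(angles) {
  n <- length(angles)
  R <- mrl_oracle(angles)
  Z <- n * R^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  min(max(p, 0), 1)
}

# Independent transcription of the time-domain HRV definitions, kept free
# of the package's functions.
hrv_oracle <- function(rr) {
  n <- length(rr)
  m <- sum(rr) / n
  d <- rr[-1] - rr[-n]
  list(
    sdnn = sqrt(sum((rr - m)^2) / (n - 1)),
    rmssd = sqrt(sum(d^2) / length(d)),
    pnn50 = 100 * sum(abs(d) > 50) / length(d),
    hr = 60000 / m
  )
}

# Density-ratio oracle for mixture memberships.
membership_oracle <- function(score, params) {
  dN <- params$w_N * stats::dnorm(score, params$mu_N, params$sigma_N)
  dI <- params$w_I * stats::dnorm(score, params$mu_I, params$sigma_I)
  list(p_N = dN / (dN + dI), p_I = dI / (dN + dI))
}
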
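#' Configuration for a simulated PAT cohort
#'
#' Bundles and validates the generative settings for [simulate_cohort()].
#' Defaults mirror the task structure used in practice: a 2-minute baseline
#' recording, 2 practice trials followed by 20 task trials, and a modest
#' rate of invalid trials (disengaged or untouched-dial) to exercise quality
#' control.
#'
#' @param n_participants Number of participants to simulate.
#' @param prop_interoceptive Expected proportion of interoceptive
#'   participants, in \[0, 1\].
#' @param kappa_range Length-2 interval (> 0) from which each interoceptive
#'   participant's von Mises concentration is drawn uniformly.
#'   Non-interoceptive participants always have kappa = 0 (uniform phases).
#' @param mu_phase Preferred phase in radians, in \[0, 2pi). `NULL` (default)
#'   draws each participant's preferred phase uniformly; a scalar fixes it
#'   for the whole cohort.
#' @param rr_mean_ms,rr_sd_ms Moments of the beat-to-beat interval
#'   distribution in ms (truncated normal, floor 300 ms).
#' @param n_task_trials,n_practice Task structure counts.
#' @param baseline_duration_s Baseline recording duration in seconds.
#' @param p_invalid_trial Per-trial probability that a task trial is injected
#'   as invalid (split evenly between the "few heart-rate samples" and
#'   "untouched dial" failure modes).
#' @param p_nonadherent Proportion of participants who do not engage with
#'   the tasks: their response phases are uniform on both tasks, so they
#'   score low on the (easy) screener and are caught by the screener gate.
#' @param screener_kappa von Mises concentration of adherent participants on
#'   the screener. The screener is an exteroceptive tone-matching task, so
#'   adherent participants respond consistently on it whether or not they
#'   are interoceptive.
#' @param seed Integer seed; identical configurations yield identical cohorts.
#' @return A validated list of class `pat_sim_config`.
#' @export
simulation_config <- function(n_participants = 200,
                              prop_interoceptive = 0.5,
                              kappa_range = c(1, 4),
                              mu_phase = NULL,
                              rr_mean_ms = 800,
                              rr_sd_ms = 50,
                              n_task_trials = 20,
                              n_practice = 2,
                              baseline_duration_s = 120,
                              p_invalid_trial = 0.05,
                              p_nonadherent = 0.05,
                              screener_kappa = 8,
                              seed = 1L) {
  stopifnot(
    n_participants >= 0,
    prop_interoceptive >= 0, prop_interoceptive <= 1,
    length(kappa_range) == 2L, all(kappa_range > 0),
    kappa_range[1] <= kappa_range[2],
    is.null(mu_phase) || (mu_phase >= 0 && mu_phase < 2 * pi),
    rr_mean_ms > 0, rr_sd_ms >= 0,
    n_task_trials >= 1, n_practice >= 0,
    baseline_duration_s > 0,
    p_invalid_trial >= 0, p_invalid_trial <= 1,
    p_nonadherent >= 0, p_nonadherent <= 1,
    screener_kappa >= 0
  )
  structure(
    list(
      n_participants = as.integer(n_participants),
      prop_interoceptive = prop_interoceptive,
      kappa_range = kappa_range,
      mu_phase = mu_phase,
      rr_mean_ms = rr_mean_ms,
      rr_sd_ms = rr_sd_ms,
      n_task_trials = as.integer(n_task_trials),
      n_practice = as.integer(n_practice),
      baseline_duration_s = baseline_duration_s,
      p_invalid_trial = p_invalid_trial,
      p_nonadherent = p_nonadherent,
      screener_kappa = screener_kappa,
      seed = as.integer(seed)
    ),
    class = "pat_sim_config"
  )
}

#' Simulate a baseline beat-timestamp series
#'
#' Beat-to-beat intervals are drawn from a normal distribution truncated at
#' a 300 ms floor (rejection sampling), and accumulated into strictly
#' increasing timestamps starting at 0 until the recording window is filled.
#'
#' @param rr_mean_ms Mean RR interval (ms), > 0.
#' @param rr_sd_ms SD of RR intervals (ms), >= 0.
#' @param duration_s Recording duration in seconds, > 0.
#' @return Strictly increasing beat timestamps in ms, starting at 0.
#' @export
simulate_rr_series <- function(rr_mean_ms, rr_sd_ms, duration_s) {
  if (!is.finite(rr_mean_ms) || rr_mean_ms <= 0) {
    stop("`rr_mean_ms` must be positive", call. = FALSE)
  }
  if (!is.finite(duration_s) || duration_s <= 0) {
    stop("`duration_s` must be positive", call. = FALSE)
  }
  if (rr_sd_ms < 0) stop("`rr_sd_ms` must be non-negative", call. = FALSE)
  duration_ms <- duration_s * 1000
  # draw in blocks; reject intervals under the 300 ms floor
  n_guess <- ceiling(duration_ms / rr_mean_ms) + 10L
  intervals <- numeric(0)
  while (sum(intervals) < duration_ms) {
    draw <- stats::rnorm(n_guess, rr_mean_ms, rr_sd_ms)
    intervals <- c(intervals, draw[draw >= 300])
  }
  ts <- cumsum(c(0, intervals))
  ts[ts <= duration_ms]
}

#' Draw from a von Mises distribution
#'
#' Best–Fisher rejection sampler. `kappa = 0` reduces to the uniform
#' distribution on the circle.
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration, >= 0.
#' @return Angles in radians in \[0, 2pi).
#' @export
rvonmises <- function(n, mu, kappa) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0L) return(numeric(0))
  if (kappa < 1e-10) return(stats::runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      u3 <- stats::runif(1)
      i <- i + 1L
      out[i] <- (sign(u3 - 0.5) * acos(f) + mu) %% (2 * pi)
    }
  }
  out
}

#' Sample a response phase for a participant profile
#'
#' Interoceptive participants respond with von Mises-concentrated phases
#' around their preferred phase; non-interoceptive participants respond
#' uniformly on the circle.
#'
#' @param profile A participant profile row (list or one-row data frame with
#'   `is_interoceptive`, `kappa`, `mu_phase`).
#' @param n Number of phases to draw.
#' @return Angles in radians in \[0, 2pi).
#' @export
sample_response_phase <- function(profile, n = 1L) {
  if (isTRUE(profile$is_interoceptive)) {
    rvonmises(n, profile$mu_phase, profile$kappa)
  } else {
    stats::runif(n, 0, 2 * pi)
  }
}

#' Convert a phase angle to a tone delay
#'
#' Inverse of [delay_to_phase()] within one cardiac cycle.
#'
#' @param angle Phase in radians, in \[0, 2pi). Vectorised.
#' @param rr_ms Cardiac cycle length in ms, > 0.
#' @return Delay in ms, in \[0, rr_ms).
#' @export
phase_to_delay <- function(angle, rr_ms) {
  if (any(!is.finite(rr_ms)) || any(rr_ms <= 0)) {
    stop("`rr_ms` must be positive", call. = FALSE)
  }
  if (any(angle < 0) || any(angle >= 2 * pi)) {
    stop("`angle` must lie in [0, 2*pi)", call. = FALSE)
  }
  rr_ms * angle / (2 * pi)
}

#' Simulate one PAT trial
#'
#' Produces a trial record in the canonical schema: instantaneous heart-rate
#' samples around the trial's reference RR, a dial-delay random walk ending
#' at the selected delay, the selected delay implied by the participant's
#' response phase, a trial duration and a confidence rating (confidence is
#' drawn independently of accuracy). Invalid-trial failure modes can be
#' injected explicitly and are labelled in the record so quality-control
#' recall is testable.
#'
#' @param profile Participant profile (see [simulate_cohort()]).
#' @param config A `pat_sim_config`.
#' @param index Trial index (1-based, across practice + task trials).
#' @param is_practice Practice-trial flag.
#' @param invalid_mode One of `"none"`, `"few_samples"` (at most 4 heart-rate
#'   values) or `"untouched_dial"` (empty delay trajectory).
#' @return A list representing one trial.
#' @export
simulate_trial <- function(profile, config, index = 1L, is_practice = FALSE,
                           invalid_mode = c("none", "few_samples", "untouched_dial")) {
  invalid_mode <- match.arg(invalid_mode)
  rr_ref <- max(300, stats::rnorm(1, config$rr_mean_ms, config$rr_sd_ms))
  theta <- sample_response_phase(profile)
  selected <- phase_to_delay(theta, rr_ref)
  duration <- stats::rlnorm(1, log(20), 0.5)

  n_hr <- if (invalid_mode == "few_samples") {
    sample(0:4, 1)
  } else {
    5L + stats::rpois(1, 15)
  }
  hr_samples <- stats::rnorm(n_hr, 60000 / rr_ref, 3)

  if (invalid_mode == "untouched_dial") {
    traj <- numeric(0)
  } else {
    # random walk over delay values, wrapped to one cycle, ending at the
    # selected delay; ~Poisson(27) unique positions
    n_pos <- max(1L, stats::rpois(1, 27))
    steps <- stats::rnorm(n_pos, 0, rr_ref / 12)
    traj <- (stats::runif(1, 0, rr_ref) + cumsum(steps)) %% rr_ref
    traj[length(traj)] <- selected
  }

  list(
    index = as.integer(index),
    is_practice = is_practice,
    hr_samples = hr_samples,
    delay_trajectory = traj,
    selected_delay_ms = selected,
    rr_reference_ms = rr_ref,
    duration_s = duration,
    confidence = sample(0:9, 1),
    injected_invalid = invalid_mode
  )
}

simulate_profile <- function(id, group, config) {
  adherent <- stats::runif(1) >= config$p_nonadherent
  is_intero <- adherent && stats::runif(1) < config$prop_interoceptive
  kappa <- if (is_intero) stats::runif(1, config$kappa_range[1], config$kappa_range[2]) else 0
  mu <- if (is.null(config$mu_phase)) stats::runif(1, 0, 2 * pi) else config$mu_phase
  # cohort ages: laboratory participants skew young, remote participants older
  age <- if (group == "laboratory") 18L + stats::rpois(1, 5) else 18L + stats::rpois(1, 13)
  list(
    participant_id = id,
    group = group,
    adherent = adherent,
    is_interoceptive = is_intero,
    kappa = kappa,
    mu_phase = mu,
    age = age,
    sex = sample(c("female", "male"), 1)
  )
}

# Response profile actually used on a given task: the screener is an easier
# exteroceptive tone-matching task, so adherent participants respond with
# high concentration on it regardless of interoceptive status.
task_profile <- function(profile, config, task) {
  if (task == "screener") {
    profile$is_interoceptive <- profile$adherent
    profile$kappa <- config$screener_kappa
  }
  profile
}

simulate_session <- function(profile, config, task) {
  profile <- task_profile(profile, config, task)
  n_total <- config$n_practice + config$n_task_trials
  trials <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    is_practice <- i <= config$n_practice
    mode <- "none"
    if (!is_practice && stats::runif(1) < config$p_invalid_trial) {
      mode <- sample(c("few_samples", "untouched_dial"), 1)
    }
    trials[[i]] <- simulate_trial(profile, config, index = i,
                                  is_practice = is_practice,
                                  invalid_mode = mode)
  }
  new_pat_session(
    participant_id = profile$participant_id,
    task = task,
    baseline_beats_ms = simulate_rr_series(config$rr_mean_ms, config$rr_sd_ms,
                                           config$baseline_duration_s),
    trials = trials_to_tibble(trials),
    meta = list(simulated = TRUE, group = profile$group,
                age = profile$age, sex = profile$sex)
  )
}

#' Simulate a full PAT cohort with ground truth
#'
#' Each participant receives a screener session and a PAT session generated
#' from the same latent profile (interoceptive status, concentration,
#' preferred phase), with participants alternately assigned to the
#' laboratory and remote groups. The ground-truth table records the latent
#' labels so downstream classification and QC can be validated.
#'
#' @param config A `pat_sim_config`.
#' @return A list with `sessions` (list of `pat_session`, two per
#'   participant) and `truth` (tibble: `participant_id`, `group`,
#'   `is_interoceptive`, `kappa`, `mu_phase`, `age`, `sex`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "pat_sim_config"))
  set.seed(config$seed)
  n <- config$n_participants
  if (n == 0L) {
    return(list(
      sessions = list(),
      truth = tibble::tibble(
        participant_id = character(), group = character(),
        is_interoceptive = logical(), kappa = numeric(),
        mu_phase = numeric(), age = integer(), sex = character()
      )
    ))
  }
  ids <- sprintf("P%03d", seq_len(n))
  groups <- rep(c("laboratory", "remote"), length.out = n)
  profiles <- purrr::map2(ids, groups, simulate_profile, config = config)
  sessions <- purrr::flatten(purrr::map(profiles, function(p) {
    list(simulate_session(p, config, "screener"),
         simulate_session(p, config, "pat"))
  }))
  truth <- purrr::map_dfr(profiles, tibble::as_tibble)
  list(sessions = sessions, truth = truth)
}

#' Write a simulated cohort to disk
#'
#' Sessions are written as one JSON file per participant-task in the
#' canonical schema; ground truth as CSV.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- purrr::map_chr(cohort$sessions, function(s) {
    path <- file.path(dir, paste0(s$participant_id, "_", s$task, ".json"))
    write_session(s, path)
    path
  })
  truth_path <- file.path(dir, "ground_truth.csv")
  utils::write.csv(cohort$truth, truth_path, row.names = FALSE)
  invisible(c(paths, truth_path))
}
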
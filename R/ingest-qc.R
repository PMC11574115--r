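#' @importFrom tibble tibble
NULL

required_trial_keys <- c("index", "is_practice", "hr_samples",
                         "delay_trajectory", "selected_delay_ms",
                         "rr_reference_ms", "duration_s", "confidence")

new_pat_session <- function(participant_id, task, baseline_beats_ms, trials,
                            meta = list()) {
  structure(
    list(
      participant_id = participant_id,
      task = task,
      baseline_beats_ms = baseline_beats_ms,
      trials = trials,
      meta = meta
    ),
    class = "pat_session"
  )
}

trials_to_tibble <- function(trials) {
  if (length(trials) == 0L) {
    return(tibble::tibble(
      index = integer(), is_practice = logical(),
      hr_samples = list(), delay_trajectory = list(),
      selected_delay_ms = numeric(), rr_reference_ms = numeric(),
      duration_s = numeric(), confidence = integer(),
      injected_invalid = character()
    ))
  }
  tibble::tibble(
    index = purrr::map_int(trials, ~ as.integer(.x$index)),
    is_practice = purrr::map_lgl(trials, ~ isTRUE(.x$is_practice)),
    hr_samples = purrr::map(trials, ~ as.numeric(.x$hr_samples)),
    delay_trajectory = purrr::map(trials, ~ as.numeric(.x$delay_trajectory)),
    selected_delay_ms = purrr::map_dbl(trials, ~ as.numeric(.x$selected_delay_ms)),
    rr_reference_ms = purrr::map_dbl(trials, ~ as.numeric(.x$rr_reference_ms)),
    duration_s = purrr::map_dbl(trials, ~ as.numeric(.x$duration_s)),
    confidence = purrr::map_int(trials, ~ as.integer(.x$confidence)),
    injected_invalid = purrr::map_chr(
      trials, ~ if (is.null(.x$injected_invalid)) "none" else .x$injected_invalid
    )
  )
}

#' @export
print.pat_session <- function(x, ...) {
  cat("<pat_session>", x$participant_id, "task:", x$task,
      "|", length(x$baseline_beats_ms), "baseline beats |",
      nrow(x$trials), "trials\n")
  invisible(x)
}

#' Parse a session record from JSON
#'
#' Reads one participant-task session in the canonical nested schema: a
#' top-level object with `participant_id`, `task` (`"screener"` or
#' `"pat"`), `baseline_beats_ms` (strictly increasing timestamps) and
#' `trials` (an ordered array of trial objects). The parser is strict:
#' missing required keys raise an error naming the key.
#'
#' @param input Path to a JSON file, or a JSON string.
#' @return A `pat_session` with trials as a tibble (one row per trial;
#'   heart-rate samples and dial trajectories as list-columns).
#' @seealso [write_session()] for the inverse.
#' @export
parse_session <- function(input) {
  raw <- jsonlite::fromJSON(input, simplifyVector = FALSE)
  for (key in c("participant_id", "task", "baseline_beats_ms", "trials")) {
    if (is.null(raw[[key]])) {
      stop("session record is missing required key `", key, "`", call. = FALSE)
    }
  }
  if (!raw$task %in% c("screener", "pat")) {
    stop("`task` must be \"screener\" or \"pat\", got \"", raw$task, "\"",
         call. = FALSE)
  }
  beats <- as.numeric(unlist(raw$baseline_beats_ms))
  if (length(beats) > 1 && any(diff(beats) <= 0)) {
    stop("`baseline_beats_ms` must be strictly increasing", call. = FALSE)
  }
  for (i in seq_along(raw$trials)) {
    missing <- setdiff(required_trial_keys, names(raw$trials[[i]]))
    if (length(missing) > 0L) {
      stop("trial ", i, " is missing required key(s): ",
           paste0("`", missing, "`", collapse = ", "), call. = FALSE)
    }
  }
  trials <- trials_to_tibble(raw$trials)
  if (is.unsorted(trials$index, strictly = TRUE)) {
    stop("trials must be ordered by strictly increasing `index`", call. = FALSE)
  }
  new_pat_session(
    participant_id = raw$participant_id,
    task = raw$task,
    baseline_beats_ms = beats,
    trials = trials,
    meta = if (is.null(raw$meta)) list() else raw$meta
  )
}

#' Write a session record as JSON
#'
#' @param session A `pat_session`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_session <- function(session, path) {
  trials <- purrr::pmap(session$trials, list)
  obj <- list(
    participant_id = session$participant_id,
    task = session$task,
    baseline_beats_ms = session$baseline_beats_ms,
    trials = trials,
    meta = session$meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Remove practice trials
#'
#' Practice trials are identified by the explicit `is_practice` flag; if no
#' trial carries the flag, the first `n_practice` trials are removed as a
#' positional fallback (reported via a message).
#'
#' @param session A `pat_session`.
#' @param n_practice Number of leading trials to drop when flags are absent.
#' @return The session without practice trials.
#' @export
remove_practice <- function(session, n_practice = 2L) {
  trials <- session$trials
  if (nrow(trials) == 0L) return(session)
  if (any(trials$is_practice)) {
    session$trials <- trials[!trials$is_practice, ]
  } else {
    message("no practice flags present; removing first ", n_practice,
            " trials positionally")
    session$trials <- trials[-seq_len(min(n_practice, nrow(trials))), ]
  }
  session
}

#' Filter invalid trials
#'
#' Applies the trial-level quality checks: trials with at most 4 heart-rate
#' values are removed (lack of engagement), and trials with an unchanged
#' dial are removed — an empty delay trajectory, or a single-entry
#' trajectory equal to the dial's default position when a
#' `default_delay_ms` is recorded in the session metadata.
#'
#' @param session A `pat_session` with practice trials removed.
#' @return A list with `session` (valid trials only) and `report`, a one-row
#'   tibble counting removals (`n_trials_in`, `n_removed_few_samples`,
#'   `n_removed_zero_delays`, `n_valid`).
#' @export
filter_valid_trials <- function(session) {
  trials <- session$trials
  n_in <- nrow(trials)
  few_samples <- purrr::map_lgl(trials$hr_samples, ~ length(.x) <= 4L)
  default_delay <- session$meta$default_delay_ms
  untouched <- purrr::map_lgl(trials$delay_trajectory, function(d) {
    length(d) == 0L ||
      (length(d) == 1L && !is.null(default_delay) && d == default_delay)
  })
  keep <- !few_samples & !untouched
  session$trials <- trials[keep, ]
  report <- tibble::tibble(
    participant_id = session$participant_id,
    task = session$task,
    n_trials_in = n_in,
    n_removed_few_samples = sum(few_samples),
    n_removed_zero_delays = sum(untouched & !few_samples),
    n_valid = sum(keep)
  )
  list(session = session, report = report)
}

#' Enforce the minimum-trial rule and truncate to a fixed trial count
#'
#' Participants with fewer than `min_trials` valid trials are excluded;
#' otherwise exactly the first `min_trials` valid trials (in task order) are
#' retained so all scored participants contribute equal trial numbers.
#' Exclusion is a value, not an error.
#'
#' @param session A `pat_session` after [filter_valid_trials()].
#' @param min_trials Minimum (and retained) number of valid trials.
#' @return A list with `session` (truncated, or `NULL` when excluded),
#'   `excluded` (flag) and `reason` (text, `NA` when retained).
#' @export
enforce_min_and_truncate <- function(session, min_trials = 17L) {
  n_valid <- nrow(session$trials)
  if (n_valid < min_trials) {
    return(list(
      session = NULL, excluded = TRUE,
      reason = sprintf("only %d valid trials (< %d required)",
                       n_valid, min_trials)
    ))
  }
  session$trials <- session$trials[seq_len(min_trials), ]
  list(session = session, excluded = FALSE, reason = NA_character_)
}

#' Engagement metrics over retained trials
#'
#' @param session A quality-controlled `pat_session`.
#' @return One-row tibble: `mean_time_per_trial_s`, `mean_dial_turns`
#'   (mean count of unique dial positions per trial), `n_valid_trials`.
#' @export
engagement <- function(session) {
  trials <- session$trials
  tibble::tibble(
    participant_id = session$participant_id,
    task = session$task,
    mean_time_per_trial_s = mean(trials$duration_s),
    mean_dial_turns = mean(purrr::map_dbl(trials$delay_trajectory,
                                          ~ length(unique(.x)))),
    n_valid_trials = nrow(trials)
  )
}

#' Screener performance gate
#'
#' Participants whose screener consistency score falls strictly below the
#' cutoff are excluded as non-adherent. The default cutoff of 0.42 is the
#' score at which the probability of being non-interoceptive is
#' approximately zero under the reference mixture, so lower screener scores
#' indicate a failure to engage with the (easier) two-tone matching task
#' rather than poor interoception.
#'
#' @param screener_score Consistency score on the screener task, in \[0, 1\].
#' @param cutoff Exclusion threshold (strict `<`).
#' @return `"retained"` or `"excluded"` (vectorised).
#' @export
screener_gate <- function(screener_score, cutoff = 0.42) {
  if (any(!is.finite(screener_score)) ||
      any(screener_score < 0) || any(screener_score > 1)) {
    stop("`screener_score` must lie in [0, 1]", call. = FALSE)
  }
  ifelse(screener_score < cutoff, "excluded", "retained")
}

#' Full quality-control cascade for one session
#'
#' Composes [remove_practice()], [filter_valid_trials()] and
#' [enforce_min_and_truncate()] and reconciles the counts into a QC report.
#'
#' @param session A raw `pat_session`.
#' @param min_trials Minimum valid trials for inclusion.
#' @return A list with `session` (`NULL` when excluded) and `report`
#'   (one-row tibble with all counts, `passed`, `reason`).
#' @export
qc_session <- function(session, min_trials = 17L) {
  n_in <- nrow(session$trials)
  no_practice <- suppressMessages(remove_practice(session))
  n_practice <- n_in - nrow(no_practice$trials)
  filt <- filter_valid_trials(no_practice)
  gate <- enforce_min_and_truncate(filt$session, min_trials = min_trials)
  report <- tibble::tibble(
    participant_id = session$participant_id,
    task = session$task,
    n_trials_in = n_in,
    n_practice_removed = n_practice,
    n_removed_few_samples = filt$report$n_removed_few_samples,
    n_removed_zero_delays = filt$report$n_removed_zero_delays,
    n_valid = filt$report$n_valid,
    passed = !gate$excluded,
    reason = gate$reason
  )
  list(session = gate$session, report = report)
}
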
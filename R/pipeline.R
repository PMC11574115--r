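#' Run the full PAT analysis pipeline
#'
#' Orchestrates the analysis end to end: session quality control, screener
#' gating, consistency scoring, baseline HRV, pooled Gaussian-mixture
#' classification with Bayes-factor thresholds, and the
#' laboratory-versus-remote comparisons (raw, age-matched, and with heart
#' rate and RMSSD regressed out). Every threshold is surfaced as a named
#' argument with its conventional value as default, and the manifest
#' accounts for every participant excluded at every stage.
#'
#' Two analysis arms are supported: the `"screened"` arm retains
#' participants with valid data on both tasks who pass the screener gate;
#' the `"unscreened"` arm retains everyone with valid PAT data regardless
#' of screener performance. The mixture is always fitted on the pooled
#' (laboratory + remote) scores of the arm before labels are split by
#' group.
#'
#' @param input A `pat_sim_config` (sessions are simulated), a directory of
#'   session JSON files, or a list of `pat_session` objects.
#' @param arm `"screened"` or `"unscreened"`.
#' @param thresholds Bayes-factor evidence thresholds.
#' @param min_trials Minimum (and retained) valid trials per session.
#' @param screener_cutoff Screener consistency cutoff (strict `<`).
#' @param out_dir Optional directory; when given, the cohort table,
#'   comparison reports, classification tables and manifest are written as
#'   CSV/JSON.
#' @return A list: `cohort` (participant-level table), `gmm` (mixture fit),
#'   `tables` (classification counts, unmatched and age-matched),
#'   `comparisons` (test reports), `qc` (per-session QC reports),
#'   `manifest` (counts, seed-bearing config echo, thresholds).
#' @export
run_pipeline <- function(input,
                         arm = c("screened", "unscreened"),
                         thresholds = c(3, 10, 30),
                         min_trials = 17L,
                         screener_cutoff = 0.42,
                         out_dir = NULL) {
  arm <- match.arg(arm)

  if (inherits(input, "pat_sim_config")) {
    sessions <- simulate_cohort(input)$sessions
    config_echo <- unclass(input)
  } else if (is.character(input) && length(input) == 1L) {
    files <- list.files(input, pattern = "\\.json$", full.names = TRUE)
    if (length(files) == 0L) {
      stop("pipeline stage `ingest`: no session JSON files in ", input,
           call. = FALSE)
    }
    sessions <- purrr::map(files, parse_session)
    config_echo <- list(input_dir = input)
  } else if (is.list(input) && all(purrr::map_lgl(input, inherits, "pat_session"))) {
    sessions <- input
    config_echo <- list(input = "in-memory sessions")
  } else {
    stop("`input` must be a pat_sim_config, a directory, or a list of sessions",
         call. = FALSE)
  }
  if (length(sessions) == 0L) {
    stop("pipeline stage `ingest`: no sessions to analyse", call. = FALSE)
  }

  # --- stage: QC + scoring, per session -------------------------------------
  qc_out <- purrr::map(sessions, qc_session, min_trials = min_trials)
  qc_reports <- purrr::map_dfr(qc_out, "report")
  kept <- purrr::compact(purrr::map(qc_out, "session"))

  session_row <- function(s) {
    sc <- session_consistency(s)
    eng <- engagement(s)
    tibble::tibble(
      participant_id = s$participant_id,
      task = s$task,
      group = s$meta$group %||% NA_character_,
      age = as.numeric(s$meta$age %||% NA_real_),
      sex = s$meta$sex %||% NA_character_,
      consistency = sc$value,
      n_trials = sc$n_trials,
      mean_time_per_trial_s = eng$mean_time_per_trial_s,
      mean_dial_turns = eng$mean_dial_turns,
      n_valid_trials = eng$n_valid_trials
    )
  }
  scored <- purrr::map_dfr(kept, session_row)
  hrv <- purrr::map_dfr(kept[purrr::map_chr(kept, "task") == "pat"],
                        session_hrv)

  pat <- scored |>
    dplyr::filter(.data$task == "pat") |>
    dplyr::left_join(hrv, by = "participant_id")
  screener <- scored |>
    dplyr::filter(.data$task == "screener") |>
    dplyr::select("participant_id", screener_score = "consistency")

  n_valid_pat <- nrow(pat)

  # --- stage: arm selection -------------------------------------------------
  if (arm == "screened") {
    cohort <- pat |>
      dplyr::inner_join(screener, by = "participant_id") |>
      dplyr::filter(screener_gate(.data$screener_score,
                                  cutoff = screener_cutoff) == "retained")
  } else {
    cohort <- dplyr::left_join(pat, screener, by = "participant_id")
  }
  if (nrow(cohort) < 10L || length(unique(cohort$group)) < 2L) {
    stop("pipeline stage `arm_selection`: too few participants (",
         nrow(cohort), ") or a missing group after the ", arm, " arm filter",
         call. = FALSE)
  }

  # --- stage: pooled mixture + Bayes factors --------------------------------
  gmm <- fit_two_component_gmm(cohort$consistency)
  memb <- gmm_membership(cohort$consistency, gmm)
  cohort <- dplyr::bind_cols(cohort, memb)
  for (th in thresholds) {
    cohort[[paste0("label_bf", th)]] <- classify_bf(cohort$bf, th)
  }

  # --- stage: comparisons ---------------------------------------------------
  matched <- age_match(cohort)
  lab <- function(d) d[d$group == "laboratory", ]
  rem <- function(d) d[d$group == "remote", ]

  compare_set <- function(d, set_name) {
    nonpar <- purrr::map_dfr(
      c("mean_time_per_trial_s", "mean_dial_turns", "n_valid_trials",
        "resting_hr_bpm", "sdnn_ms", "rmssd_ms", "pnn50_pct", "age"),
      function(v) {
        dplyr::mutate(mann_whitney(lab(d)[[v]], rem(d)[[v]]),
                      measure = v, .before = 1)
      }
    )
    tt <- dplyr::mutate(students_t(lab(d)$consistency, rem(d)$consistency),
                        measure = "consistency", .before = 1)
    sex_tab <- rbind(table(factor(lab(d)$sex, c("male", "female"))),
                     table(factor(rem(d)$sex, c("male", "female"))))
    sex_chi <- dplyr::mutate(suppressWarnings(chi_square(sex_tab)),
                             measure = "sex", .before = 1)
    dplyr::bind_rows(nonpar, tt, dplyr::select(sex_chi, -"expected")) |>
      dplyr::mutate(sample = set_name, .before = 1)
  }

  class_chi <- function(d, set_name) {
    purrr::map_dfr(thresholds, function(th) {
      counts <- rbind(
        table(factor(lab(d)[[paste0("label_bf", th)]],
                     c("non-interoceptive", "unclassified", "interoceptive"))),
        table(factor(rem(d)[[paste0("label_bf", th)]],
                     c("non-interoceptive", "unclassified", "interoceptive")))
      )
      keep <- colSums(counts) > 0   # labels unused by both groups drop out
      res <- if (sum(keep) < 2L) {
        tibble::tibble(test = "chi_square", statistic = NA_real_,
                       df = NA_real_, p_value = NA_real_)
      } else {
        dplyr::select(suppressWarnings(chi_square(counts[, keep, drop = FALSE])),
                      -"expected")
      }
      dplyr::mutate(res, sample = set_name, threshold = th, .before = 1)
    })
  }

  comparisons <- dplyr::bind_rows(
    compare_set(cohort, "unmatched"),
    compare_set(matched, "age_matched"),
    dplyr::mutate(residualized_compare(matched),
                  measure = "consistency_residualized",
                  sample = "age_matched", .before = 1),
    class_chi(cohort, "unmatched"),
    class_chi(matched, "age_matched")
  )

  tables <- dplyr::bind_rows(
    dplyr::mutate(classification_table(cohort, thresholds),
                  sample = "unmatched", .before = 1),
    dplyr::mutate(classification_table(matched, thresholds),
                  sample = "age_matched", .before = 1)
  )

  manifest <- list(
    arm = arm,
    thresholds = thresholds,
    min_trials = min_trials,
    screener_cutoff = screener_cutoff,
    config = config_echo,
    counts = list(
      n_sessions_in = length(sessions),
      n_sessions_passed_qc = length(kept),
      n_sessions_failed_qc = length(sessions) - length(kept),
      n_valid_pat = n_valid_pat,
      n_cohort = nrow(cohort),
      n_age_matched = nrow(matched),
      n_by_group = as.list(table(cohort$group))
    )
  )

  result <- list(cohort = cohort, matched = matched, gmm = gmm,
                 tables = tables, comparisons = comparisons,
                 qc = qc_reports, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                     row.names = FALSE)
    utils::write.csv(tables, file.path(out_dir, "classification_tables.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    utils::write.csv(qc_reports, file.path(out_dir, "qc_reports.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a
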
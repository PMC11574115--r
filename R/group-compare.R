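#' @importFrom dplyr .data
NULL

#' Match laboratory and remote groups on age
#'
#' The laboratory cohort skews young and the remote cohort older, so groups
#' are matched on average by trimming the tails: remote participants aged
#' 30 years and over are removed, laboratory participants under 19 years
#' are removed, and laboratory participants at or above the outlier age are
#' removed. The operation is idempotent.
#'
#' @param cohort Tibble with one row per participant, columns `group`
#'   (`"laboratory"`/`"remote"`) and `age`.
#' @param remote_max_age Oldest remote age retained.
#' @param lab_min_age Youngest laboratory age retained.
#' @param lab_outlier_age Laboratory ages at or above this are removed as
#'   outliers.
#' @return The trimmed cohort.
#' @export
age_match <- function(cohort, remote_max_age = 29, lab_min_age = 19,
                      lab_outlier_age = 63) {
  missing_age <- !is.finite(cohort$age)
  if (any(missing_age)) {
    stop("missing ages for participant(s): ",
         paste(cohort$participant_id[missing_age], collapse = ", "),
         call. = FALSE)
  }
  cohort |>
    dplyr::filter(
      !(.data$group == "remote" & .data$age > remote_max_age),
      !(.data$group == "laboratory" & .data$age < lab_min_age),
      !(.data$group == "laboratory" & .data$age >= lab_outlier_age)
    )
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with the pooled variance estimate, so the degrees of freedom
#' are always `n1 + n2 - 2`. Welch's unequal-variance version is available
#' via `var_equal = FALSE`.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @param var_equal Pool the variances (default).
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`, `mean_x`,
#'   `mean_y`, `sd_x`, `sd_y`, `n_x`, `n_y`.
#' @export
students_t <- function(x, y, var_equal = TRUE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples need at least 2 observations", call. = FALSE)
  }
  fit <- stats::t.test(x, y, var.equal = var_equal)
  tibble::tibble(
    test = if (var_equal) "students_t" else "welch_t",
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value,
    mean_x = mean(x), mean_y = mean(y),
    sd_x = stats::sd(x), sd_y = stats::sd(y),
    n_x = length(x), n_y = length(y)
  )
}

#' Mann-Whitney U test with normal approximation
#'
#' Rank-sum test reported as the U statistic and a standardised Z with the
#' tie-corrected variance (no continuity correction), with a two-sided
#' normal p-value — the convention of mainstream statistical software for
#' moderate samples.
#'
#' @param x,y Numeric samples, both non-empty.
#' @return One-row tibble: `test`, `statistic` (U for `x`), `z`, `p_value`,
#'   medians and ns.
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n1 <- length(x)
  n2 <- length(y)
  n <- n1 + n2
  r <- rank(c(x, y))
  u1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu_u <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  var_u <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  z <- if (var_u == 0) 0 else (u1 - mu_u) / sqrt(var_u)
  tibble::tibble(
    test = "mann_whitney",
    statistic = u1,
    z = z,
    p_value = 2 * stats::pnorm(-abs(z)),
    median_x = stats::median(x), median_y = stats::median(y),
    n_x = n1, n_y = n2
  )
}

#' Pearson chi-square test on a contingency table
#'
#' Plain Pearson X-squared without continuity correction, for 2 x k count
#' tables (k = 2 or 3). Small expected counts trigger a warning, not an
#' error.
#'
#' @param counts Non-negative integer matrix, 2 rows, 2 or 3 columns.
#' @return One-row tibble: `test`, `statistic`, `df`, `p_value`, plus the
#'   expected-count matrix in the list-column `expected`.
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L || !ncol(counts) %in% c(2L, 3L)) {
    stop("`counts` must be a 2 x 2 or 2 x 3 table", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must contain non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("`counts` has a zero marginal; the test is undefined", call. = FALSE)
  }
  fit <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  if (any(fit$expected < 5)) {
    warning("expected counts below 5; chi-square approximation may be poor",
            call. = FALSE)
  }
  tibble::tibble(
    test = "chi_square",
    statistic = unname(fit$statistic),
    df = unname(fit$parameter),
    p_value = fit$p.value,
    expected = list(fit$expected)
  )
}

#' Group comparison of consistency after regressing out physiology
#'
#' Fits a pooled ordinary least squares regression of consistency on
#' resting heart rate and RMSSD (with intercept, across both groups), and
#' compares the residuals between groups with the pooled t-test. This is
#' the control analysis for group differences in cardiac physiology.
#'
#' @param cohort Tibble with columns `group`, `consistency`,
#'   `resting_hr_bpm`, `rmssd_ms`, all complete.
#' @param covariates Column names to regress out.
#' @return One-row tibble as from [students_t()], with `test` set to
#'   `"residualized_t"`.
#' @export
residualized_compare <- function(cohort,
                                 covariates = c("resting_hr_bpm", "rmssd_ms")) {
  need <- c("group", "consistency", covariates)
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols) > 0L) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(cohort[, covariates])
  if (any(!is.finite(X)) || any(!is.finite(cohort$consistency))) {
    stop("covariates and consistency must be complete", call. = FALSE)
  }
  if (kappa(cbind(1, X), exact = TRUE) > 1e8) {
    stop("covariates are (near-)collinear", call. = FALSE)
  }
  form <- stats::reformulate(covariates, response = "consistency")
  fit <- stats::lm(form, data = cohort)
  res <- stats::residuals(fit)
  out <- students_t(res[cohort$group == "laboratory"],
                    res[cohort$group == "remote"])
  out$test <- "residualized_t"
  out
}
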
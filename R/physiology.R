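#' Beat timestamps to RR-interval series
#'
#' @param beats_ms Strictly increasing beat timestamps in milliseconds,
#'   at least 3 beats.
#' @return Numeric vector of successive beat-to-beat intervals (ms), of
#'   length `length(beats_ms) - 1`.
#' @export
#' @examples
#' timestamps_to_rr(c(0, 800, 1600)) # c(800, 800)
timestamps_to_rr <- function(beats_ms) {
  if (length(beats_ms) < 3L) {
    stop("need at least 3 beat timestamps", call. = FALSE)
  }
  d <- diff(beats_ms)
  bad <- which(d <= 0)
  if (length(bad) > 0L) {
    stop(
      "beat timestamps not strictly increasing at position ", bad[1] + 1L,
      call. = FALSE
    )
  }
  if (any(d < 300 | d > 2000)) {
    warning(
      sum(d < 300 | d > 2000),
      " RR interval(s) outside the physiological range [300, 2000] ms; ",
      "retained without correction",
      call. = FALSE
    )
  }
  d
}

#' Time-domain heart rate variability metrics
#'
#' Standard time-domain summaries of an RR-interval series:
#' \describe{
#'   \item{`sdnn()`}{sample standard deviation of the RR intervals
#'     (n - 1 denominator), in ms.}
#'   \item{`rmssd()`}{root mean square of successive RR differences, in ms.}
#'   \item{`pnn50()`}{percentage of successive differences strictly exceeding
#'     50 ms in absolute value.}
#'   \item{`resting_hr()`}{mean heart rate, `60000 / mean(rr)`, in bpm.}
#' }
#'
#' @param rr Numeric vector of RR intervals in milliseconds, all positive.
#'   `sdnn()` and `resting_hr()` need at least 2 intervals; `rmssd()` and
#'   `pnn50()` need at least 3 (two successive differences).
#' @return A scalar; see the individual descriptions for units.
#' @name hrv_timedomain
#' @examples
#' rr <- c(800, 850, 790)
#' rmssd(rr) # sqrt((50^2 + 60^2) / 2)
#' pnn50(c(800, 900, 905)) # differences 100, 5 -> 50%
NULL

check_rr <- function(rr, min_n) {
  if (length(rr) < min_n) {
    stop("need at least ", min_n, " RR intervals", call. = FALSE)
  }
  if (any(!is.finite(rr)) || any(rr <= 0)) {
    stop("RR intervals must be positive and finite", call. = FALSE)
  }
  invisible(rr)
}

#' @rdname hrv_timedomain
#' @export
sdnn <- function(rr) {
  check_rr(rr, 2L)
  stats::sd(rr)
}

#' @rdname hrv_timedomain
#' @export
rmssd <- function(rr) {
  check_rr(rr, 3L)
  sqrt(mean(diff(rr)^2))
}

#' @rdname hrv_timedomain
#' @export
pnn50 <- function(rr) {
  check_rr(rr, 3L)
  d <- abs(diff(rr))
  100 * mean(d > 50)
}

#' @rdname hrv_timedomain
#' @export
resting_hr <- function(rr) {
  check_rr(rr, 2L)
  60000 / mean(rr)
}

#' HRV metrics for a session's baseline recording
#'
#' Extracts the RR series from the 2-minute baseline beat timestamps and
#' computes the time-domain metrics. Trial-period beats are never used.
#'
#' @param session A `pat_session` with a `baseline_beats_ms` field.
#' @return A one-row tibble: `participant_id`, `sdnn_ms`, `rmssd_ms`,
#'   `pnn50_pct`, `resting_hr_bpm`.
#' @export
session_hrv <- function(session) {
  rr <- timestamps_to_rr(session$baseline_beats_ms)
  tibble::tibble(
    participant_id = session$participant_id,
    sdnn_ms = sdnn(rr),
    rmssd_ms = rmssd(rr),
    pnn50_pct = pnn50(rr),
    resting_hr_bpm = resting_hr(rr)
  )
}
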
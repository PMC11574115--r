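#' Convert a selected tone delay to a phase angle on the cardiac cycle
#'
#' A delay of one full cardiac cycle (the reference RR interval) corresponds
#' to a phase of \eqn{2\pi}; delays longer than one cycle wrap around. The
#' reference interval is the mean RR interval of the trial on which the delay
#' was selected, so that phase is defined relative to the concurrent cardiac
#' rhythm rather than the resting baseline.
#'
#' @param selected_delay_ms Selected tone delay in milliseconds (>= 0).
#'   Vectorised.
#' @param rr_reference_ms Reference RR interval in milliseconds (> 0).
#'   Recycled against `selected_delay_ms`.
#' @return Phase angle(s) in radians, in the half-open interval \[0, 2pi).
#' @seealso [mean_resultant_length()], [session_consistency()]
#' @export
#' @examples
#' delay_to_phase(400, 800) # half a cycle -> pi
#' delay_to_phase(1000, 800) # wraps: 200/800 of a cycle -> pi/2
delay_to_phase <- function(selected_delay_ms, rr_reference_ms) {
  if (any(!is.finite(rr_reference_ms)) || any(rr_reference_ms <= 0)) {
    stop("`rr_reference_ms` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(selected_delay_ms)) || any(selected_delay_ms < 0)) {
    stop("`selected_delay_ms` must be non-negative and finite", call. = FALSE)
  }
  theta <- 2 * pi * ((selected_delay_ms %% rr_reference_ms) / rr_reference_ms)
  # guard against 2*pi arising from floating-point mod at the boundary
  theta %% (2 * pi)
}

#' Mean resultant length of a set of phase angles
#'
#' The magnitude of the average unit vector of the angles: 1 when all angles
#' coincide, and tending to 0 as the angles disperse uniformly around the
#' circle. This is the consistency statistic summarising cross-trial phase
#' agreement.
#'
#' @param angles Numeric vector of angles in radians (any real values;
#'   wrapping is implicit in the trigonometry). At least one angle required.
#' @return A scalar in \[0, 1\].
#' @export
#' @examples
#' mean_resultant_length(c(pi / 3, pi / 3, pi / 3)) # 1
#' mean_resultant_length(c(0, pi)) # 0, antipodal cancellation
mean_resultant_length <- function(angles) {
  if (length(angles) == 0L) {
    stop("`angles` must contain at least one angle", call. = FALSE)
  }
  if (any(!is.finite(angles))) {
    stop("`angles` must be finite", call. = FALSE)
  }
  sqrt(mean(cos(angles))^2 + mean(sin(angles))^2)
}

#' Consistency score for a quality-controlled session
#'
#' Maps each retained trial's selected delay to a phase angle via
#' [delay_to_phase()] (using the trial's own mean RR interval as reference)
#' and summarises cross-trial agreement as the mean resultant length.
#' Sessions are expected to have passed quality control so that every
#' retained trial carries a selected delay and an RR reference.
#'
#' @param session A `pat_session`, after QC (see [qc_session()]).
#' @return A list with `value` (consistency in \[0, 1\]) and `n_trials`.
#' @export
session_consistency <- function(session) {
  trials <- session$trials
  if (nrow(trials) == 0L) {
    stop("session has no trials to score", call. = FALSE)
  }
  bad <- which(!is.finite(trials$rr_reference_ms) | trials$rr_reference_ms <= 0)
  if (length(bad) > 0L) {
    stop(
      "missing or invalid rr_reference_ms on trial(s): ",
      paste(trials$index[bad], collapse = ", "),
      call. = FALSE
    )
  }
  theta <- delay_to_phase(trials$selected_delay_ms, trials$rr_reference_ms)
  list(value = mean_resultant_length(theta), n_trials = nrow(trials))
}
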
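#' Fit a two-component Gaussian mixture to consistency scores
#'
#' Expectation-maximisation for a two-component univariate Gaussian mixture,
#' pooled across the whole sample. Initialisation is deterministic: scores
#' are split at their median and each half supplies its component's starting
#' mean and SD, with equal starting weights. Components are relabelled after
#' convergence so the lower-mean component is the non-interoceptive one
#' (`_N`) and the higher-mean component the interoceptive one (`_I`).
#' Component SDs are floored at `sigma_floor` to prevent variance collapse;
#' a fit that ends with an SD at the floor or a vanishing weight is flagged
#' degenerate rather than failing silently.
#'
#' @param scores Numeric vector of consistency scores in \[0, 1\]; at least
#'   10 required.
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param max_iter Maximum EM iterations.
#' @param sigma_floor Lower bound for component SDs.
#' @return A list of class `pat_gmm`: `w_N`, `w_I`, `mu_N`, `mu_I`,
#'   `sigma_N`, `sigma_I`, `loglik`, `loglik_trace`, `n_iter`, `converged`,
#'   `degenerate`.
#' @export
fit_two_component_gmm <- function(scores, tol = 1e-8, max_iter = 1000L,
                                  sigma_floor = 1e-4) {
  if (length(scores) < 10L) {
    stop("need at least 10 scores to fit the mixture", call. = FALSE)
  }
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1)) {
    stop("`scores` must lie in [0, 1]", call. = FALSE)
  }
  n <- length(scores)
  med <- stats::median(scores)
  lower <- scores[scores <= med]
  upper <- scores[scores > med]
  if (length(upper) == 0L) {       # all scores tied at the median
    lower <- scores
    upper <- scores
  }
  mu <- c(mean(lower), mean(upper))
  sigma <- pmax(c(stats::sd(lower), stats::sd(upper)), sigma_floor,
                na.rm = TRUE)
  sigma[is.na(sigma)] <- sigma_floor
  w <- c(0.5, 0.5)

  comp_dens <- function() {
    cbind(w[1] * stats::dnorm(scores, mu[1], sigma[1]),
          w[2] * stats::dnorm(scores, mu[2], sigma[2]))
  }
  dens <- comp_dens()
  ll <- sum(log(rowSums(dens)))
  trace <- ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E step: responsibilities
    resp <- dens / rowSums(dens)
    # M step
    nk <- colSums(resp)
    w <- nk / n
    mu <- colSums(resp * scores) / nk
    sigma <- sqrt(colSums(resp * outer(scores, mu, "-")^2) / nk)
    sigma <- pmax(sigma, sigma_floor)
    dens <- comp_dens()
    ll_new <- sum(log(rowSums(dens)))
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < tol) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }

  ord <- order(mu)   # non-interoceptive = lower mean
  degenerate <- any(sigma <= sigma_floor) || any(w < 0.01)
  structure(
    list(
      w_N = w[ord[1]], w_I = w[ord[2]],
      mu_N = mu[ord[1]], mu_I = mu[ord[2]],
      sigma_N = sigma[ord[1]], sigma_I = sigma[ord[2]],
      loglik = ll, loglik_trace = trace, n_iter = iter,
      converged = converged, degenerate = degenerate
    ),
    class = "pat_gmm"
  )
}

#' @export
print.pat_gmm <- function(x, ...) {
  cat(sprintf(
    "<pat_gmm> N: w=%.3f mu=%.3f sd=%.3f | I: w=%.3f mu=%.3f sd=%.3f | loglik=%.3f (%d iter)%s\n",
    x$w_N, x$mu_N, x$sigma_N, x$w_I, x$mu_I, x$sigma_I,
    x$loglik, x$n_iter, if (x$degenerate) " [degenerate]" else ""
  ))
  invisible(x)
}

#' Membership probabilities and Bayes factor for a score
#'
#' Standardises the score against each fitted component
#' (\eqn{z_k = (x - \mu_k)/\sigma_k}) and converts the standardised scores
#' into membership probabilities. By default these are the posterior
#' responsibilities (component weights times normal densities, normalised);
#' `weighted = FALSE` gives the unweighted density ratio instead. The Bayes
#' factor is the ratio of the interoceptive to the non-interoceptive
#' membership probability.
#'
#' Probabilities and the Bayes factor are computed in log space, with the
#' log Bayes factor clamped to +/- 700 so that extreme scores yield finite,
#' strictly positive Bayes factors instead of floating-point under/overflow.
#'
#' @param score Consistency score(s).
#' @param params A non-degenerate `pat_gmm` fit.
#' @param weighted Use mixture weights when forming probabilities (default).
#' @return A tibble with one row per score: `z_N`, `z_I`, `p_N`, `p_I`, `bf`.
#' @export
gmm_membership <- function(score, params, weighted = TRUE) {
  stopifnot(inherits(params, "pat_gmm"))
  if (isTRUE(params$degenerate)) {
    stop("mixture fit is degenerate; memberships are not defined",
         call. = FALSE)
  }
  z_N <- (score - params$mu_N) / params$sigma_N
  z_I <- (score - params$mu_I) / params$sigma_I
  ld_N <- stats::dnorm(z_N, log = TRUE) - log(params$sigma_N)
  ld_I <- stats::dnorm(z_I, log = TRUE) - log(params$sigma_I)
  if (weighted) {
    ld_N <- ld_N + log(params$w_N)
    ld_I <- ld_I + log(params$w_I)
  }
  lbf <- pmin(pmax(ld_I - ld_N, -700), 700)
  # each probability from its own logistic form, so tiny memberships are
  # kept to full relative precision rather than lost against 1
  tibble::tibble(z_N = z_N, z_I = z_I,
                 p_N = 1 / (1 + exp(lbf)), p_I = 1 / (1 + exp(-lbf)),
                 bf = exp(lbf))
}

#' Classify a Bayes factor at an evidence threshold
#'
#' Strict thresholds: `bf > threshold` classifies as interoceptive,
#' `bf < 1/threshold` as non-interoceptive, anything in between (including
#' a Bayes factor exactly at the threshold) as unclassified. Thresholds of
#' 3, 10 and 30 correspond to moderate, strong and very strong evidence.
#'
#' @param bf Bayes factor(s), > 0.
#' @param threshold Evidence threshold, > 1.
#' @return Character vector: `"interoceptive"`, `"non-interoceptive"` or
#'   `"unclassified"`.
#' @export
classify_bf <- function(bf, threshold) {
  if (any(!is.nan(bf) & bf <= 0)) {
    stop("`bf` must be positive", call. = FALSE)
  }
  stopifnot(length(threshold) == 1L, threshold > 1)
  dplyr::case_when(
    bf > threshold ~ "interoceptive",
    bf < 1 / threshold ~ "non-interoceptive",
    TRUE ~ "unclassified"
  )
}

#' Classification counts by group, label and threshold
#'
#' @param memberships Tibble with columns `group` and `bf` (one row per
#'   participant).
#' @param thresholds Evidence thresholds to tabulate at.
#' @return Tibble: `threshold`, `group`, `non_interoceptive`, `unclassified`,
#'   `interoceptive`, `n`. Row counts always sum to the group size.
#' @export
classification_table <- function(memberships, thresholds = c(3, 10, 30)) {
  purrr::map_dfr(thresholds, function(th) {
    labels <- classify_bf(memberships$bf, th)
    memberships |>
      dplyr::mutate(label = labels) |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(
        threshold = th,
        non_interoceptive = sum(.data$label == "non-interoceptive"),
        unclassified = sum(.data$label == "unclassified"),
        interoceptive = sum(.data$label == "interoceptive"),
        n = dplyr::n(),
        .groups = "drop"
      ) |>
      dplyr::relocate("threshold")
  })
}
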
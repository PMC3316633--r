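#' Hit and false-alarm rates from visibility responses
#'
#' Detection test: a hit is a "yes" response on a trial where an image was
#' presented; a false alarm is a "yes" on a no-image trial. Identification
#' test (scored as Apple versus the rest): a hit is an "apple" response on
#' an Apple trial; a false alarm is an "apple" response when a different
#' image was shown.
#'
#' @param responses Data frame from [simulate_visibility()] or with the
#'   same columns (`signal` logical, `response` character) and a `test`
#'   attribute.
#' @return Named numeric vector `c(hit_rate, fa_rate)`.
#' @export
rates_from_responses <- function(responses) {
  test <- attr(responses, "test")
  if (is.null(test)) stop("responses lack a 'test' attribute")
  yes <- responses$response == if (test == "detection") "yes" else "apple"
  sig <- responses$signal
  if (!any(sig) || all(sig)) stop("need at least one signal and one noise trial")
  c(hit_rate = mean(yes[sig]), fa_rate = mean(yes[!sig]))
}

#' Signal-detection sensitivity d'
#'
#' `d' = z(hit) - z(fa)` with the standard normal quantile. When either
#' rate is exactly 0 or 1 the statistic is undefined and `NA` is returned
#' (not an error), matching the convention of reporting such subjects as
#' non-computable. `loglinear = TRUE` applies the log-linear correction
#' (add 0.5 to counts) instead, which always yields a finite value.
#'
#' @param hit_rate,fa_rate Rates in \[0, 1\].
#' @param n_signal,n_noise Trial counts, required for the correction.
#' @param loglinear Apply the log-linear rate correction.
#' @return d' or `NA` when undefined.
#' @export
d_prime <- function(hit_rate, fa_rate, n_signal = NULL, n_noise = NULL,
                    loglinear = FALSE) {
  if (any(c(hit_rate, fa_rate) < 0 | c(hit_rate, fa_rate) > 1))
    stop("rates must lie in [0, 1]")
  if (loglinear) {
    if (is.null(n_signal) || is.null(n_noise))
      stop("loglinear correction needs trial counts")
    hit_rate <- (hit_rate * n_signal + 0.5) / (n_signal + 1)
    fa_rate <- (fa_rate * n_noise + 0.5) / (n_noise + 1)
  }
  if (hit_rate %in% c(0, 1) || fa_rate %in% c(0, 1)) return(NA_real_)
  stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
}

#' Bootstrap confidence interval for d'
#'
#' Percentile interval over `n_boot` resamples of the subject's responses
#' (trials resampled with replacement within the signal and noise classes,
#' so both classes are present in every resample). Resamples with an
#' undefined d' (a rate of exactly 0 or 1) are dropped from the interval
#' and counted; if every resample is undefined the interval is `NA` with a
#' warning.
#'
#' @param responses As in [rates_from_responses()].
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return List of class `dprime_result`: `d_prime`, `hit_rate`, `fa_rate`,
#'   `ci_low`, `ci_high`, `n_boot`, `n_undefined`, `chance_consistent`
#'   (interval contains 0).
#' @export
bootstrap_dprime_ci <- function(responses, n_boot = 1000, level = 0.95,
                                seed = 1L) {
  if (n_boot < 1) stop("n_boot must be at least 1")
  rates <- rates_from_responses(responses)
  test <- attr(responses, "test")
  yes <- responses$response == if (test == "detection") "yes" else "apple"
  sig_yes <- yes[responses$signal]
  noi_yes <- yes[!responses$signal]
  n_s <- length(sig_yes); n_n <- length(noi_yes)
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(seed)
  hit_b <- colMeans(matrix(sig_yes[sample.int(n_s, n_s * n_boot, replace = TRUE)],
                           n_s, n_boot))
  fa_b <- colMeans(matrix(noi_yes[sample.int(n_n, n_n * n_boot, replace = TRUE)],
                          n_n, n_boot))
  ok <- hit_b > 0 & hit_b < 1 & fa_b > 0 & fa_b < 1
  d_b <- stats::qnorm(hit_b[ok]) - stats::qnorm(fa_b[ok])
  alpha <- (1 - level) / 2
  if (length(d_b) == 0) {
    warning("all bootstrap resamples yielded undefined d'")
    ci <- c(NA_real_, NA_real_)
  } else {
    ci <- unname(stats::quantile(d_b, c(alpha, 1 - alpha)))
  }
  d_hat <- d_prime(rates["hit_rate"], rates["fa_rate"])
  structure(list(d_prime = unname(d_hat), hit_rate = unname(rates["hit_rate"]),
                 fa_rate = unname(rates["fa_rate"]),
                 ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
                 n_undefined = sum(!ok),
                 chance_consistent = if (anyNA(ci)) NA else ci[1] <= 0 && ci[2] >= 0),
            class = "dprime_result")
}

#' @export
print.dprime_result <- function(x, ...) {
  cat(sprintf("d' = %s (hit %.3f, fa %.3f), %d%% CI [%s, %s], chance-consistent: %s\n",
              format(round(x$d_prime, 3)), x$hit_rate, x$fa_rate, 95,
              format(round(x$ci_low, 3)), format(round(x$ci_high, 3)),
              format(x$chance_consistent)))
  invisible(x)
}

#' Conjunction awareness criterion over the two visibility tests
#'
#' A subject counts as aware only when both tests' confidence intervals
#' exclude zero; a single chance-inconsistent test does not flag awareness.
#'
#' @param test1,test2 `dprime_result` objects (detection, identification).
#' @return List: `aware` (logical), per-test `chance_consistent` flags.
#' @export
assess_awareness <- function(test1, test2) {
  stopifnot(inherits(test1, "dprime_result"), inherits(test2, "dprime_result"))
  cc <- c(test1 = test1$chance_consistent, test2 = test2$chance_consistent)
  aware <- isFALSE(cc[["test1"]]) && isFALSE(cc[["test2"]])
  list(aware = aware, chance_consistent = cc)
}
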
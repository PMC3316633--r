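#' Hyperbolic subjective value of a delayed reward
#'
#' Computes `SV = R / (1 + k * D)`: the present subjective value of a reward
#' of `amount` dollars received after `delay` days, discounted hyperbolically
#' at per-day rate `k`.
#'
#' @param amount Delayed reward magnitude in dollars (> 0). Vectorised.
#' @param delay Delay in days (>= 0). Vectorised.
#' @param k Per-day discount rate (>= 0). Larger `k` means steeper devaluation
#'   of future rewards (more impulsive).
#' @return Subjective value in dollars, same length as the longest argument.
#' @examples
#' subjective_value(106.40, 180, 0.024)  # 20: the indifference amount
#' subjective_value(50, 0, 0.024)        # zero delay leaves value undiscounted
#' @export
subjective_value <- function(amount, delay, k) {
  stopifnot(is.numeric(amount), is.numeric(delay), is.numeric(k))
  if (any(amount <= 0)) stop("amount must be positive")
  if (any(delay < 0)) stop("delay must be non-negative")
  if (any(k < 0)) stop("discount rate k must be non-negative")
  amount / (1 + k * delay)
}

#' Prime-conditional subjective value
#'
#' On trials preceded by the rewarding brand prime the discount rate is
#' shifted by an additive premium `a`: `SV* = R / (1 + (k + a * I_A) * D)`,
#' where the indicator `I_A` is 1 on Apple-prime trials and 0 otherwise.
#' Reduces to [subjective_value()] when `is_apple` is `FALSE` or `a = 0`.
#'
#' @inheritParams subjective_value
#' @param a Premium on the discount rate (1/day); may be negative but the
#'   effective rate `k + a` must stay non-negative on Apple trials.
#' @param is_apple Logical; whether the trial carried the rewarding prime.
#' @return Primed subjective value in dollars.
#' @export
primed_subjective_value <- function(amount, delay, k, a, is_apple) {
  stopifnot(is.logical(is_apple) || all(is_apple %in% c(0, 1)))
  k_eff <- k + a * as.numeric(is_apple)
  if (any(k_eff < 0)) stop("effective discount rate k + a must be non-negative on primed trials")
  subjective_value(amount, delay, k_eff)
}

#' Logistic choice probability for the delayed option
#'
#' `P(later) = logistic(omega * (SV_delayed - immediate))`. `omega` is the
#' choice sensitivity (inverse decision noise, units 1/dollar): for large
#' `omega` choices become deterministic at the indifference point, for small
#' `omega` they approach coin flips.
#'
#' @param sv_delayed Subjective value of the delayed option, dollars.
#' @param omega Choice sensitivity (> 0), 1/dollar.
#' @param immediate Value of the immediate option, dollars (default 20).
#' @return Probability in (0, 1) of choosing the delayed option.
#' @export
choice_probability <- function(sv_delayed, omega, immediate = 20) {
  if (any(omega <= 0)) stop("omega must be positive")
  stats::plogis(omega * (sv_delayed - immediate))
}

#' Delayed amount at the indifference point
#'
#' Inverts the hyperbolic value function at `SV = immediate`: the delayed
#' amount `immediate * (1 + k * D)` for which now and later are chosen with
#' equal probability under any sensitivity `omega`.
#'
#' @inheritParams subjective_value
#' @param immediate Immediate amount in dollars (default 20).
#' @export
indifference_amount <- function(delay, k, immediate = 20) {
  if (any(delay < 0)) stop("delay must be non-negative")
  if (any(k < 0)) stop("discount rate k must be non-negative")
  immediate * (1 + k * delay)
}

#' Difficulty index of a discounting choice
#'
#' Maps the value distance `delta = SV - immediate` to a difficulty score
#' `Gamma(delta) = 1 - |2 P(delta) - 1| = 2 min(P, 1 - P)` with
#' `P = logistic(omega * delta)`. Gamma lies in \[0, 1\], is maximal (1) when
#' the delayed option's subjective value equals the immediate amount, falls
#' to 0 as |delta| grows, and is even in delta.
#'
#' @param delta Value distance `SV - immediate`, dollars. Vectorised.
#' @param omega Choice sensitivity (> 0).
#' @export
difficulty_index <- function(delta, omega) {
  p <- choice_probability(delta + 20, omega, immediate = 20)
  1 - abs(2 * p - 1)
}

#' @rdname discount_params
#' @param k,a,omega See field descriptions below.
#' @export
discount_params <- function(k, a = 0, omega) {
  stopifnot(length(k) == 1, length(a) == 1, length(omega) == 1)
  if (k < 0) stop("k must be non-negative")
  if (omega <= 0) stop("omega must be positive")
  if (k + a < 0) stop("primed rate k + a must be non-negative")
  structure(list(k = k, a = a, omega = omega), class = "discount_params")
}

#' Discounting parameter triple
#'
#' Container for a subject's discounting parameters: discount rate `k`
#' (1/day, >= 0), priming premium `a` on the rate (1/day; `k + a >= 0`), and
#' choice sensitivity `omega` (1/dollar, > 0).
#'
#' @name discount_params
#' @param x,... Print method arguments.
#' @export
print.discount_params <- function(x, ...) {
  cat(sprintf("discounting parameters: k = %.4g, a = %.4g, omega = %.4g\n",
              x$k, x$a, x$omega))
  invisible(x)
}

check_td_trials <- function(trials) {
  needed <- c("trial_type", "prime", "amount", "delay")
  missing <- setdiff(needed, names(trials))
  if (length(missing)) stop("trial table lacks columns: ", paste(missing, collapse = ", "))
  trials
}

#' Per-trial derived model quantities
#'
#' Given a trial table and a subject's fitted parameters, computes for every
#' temporal-discounting (TD) trial: the subjective value `sv`, the primed
#' value `sv_star`, the trial premium `pi = sv_star - sv` (zero on neutral
#' trials by construction), the prime-by-value interaction
#' `sigma = a * sv_star`, the value distance `delta = sv - immediate`, the
#' difficulty index `gamma`, and a `hard` label from the subject's median
#' split on `gamma` (strict inequality: ties at the median are easy).
#' Perceptual-control trials carry `NA` throughout (no value semantics).
#'
#' @param trials Data frame with columns `trial_type` ("TD"/"PC"), `prime`
#'   ("apple"/"cup"/"control"), `amount`, `delay`.
#' @param params A [discount_params] object (typically a fitted triple).
#' @param immediate Immediate amount, dollars.
#' @param sigma_on_cup If `TRUE` (default) the interaction is evaluated as
#'   written on every TD trial (on cup trials `sv_star = sv`); if `FALSE` it
#'   is zeroed on cup trials.
#' @return `trials` with columns `sv`, `sv_star`, `pi`, `sigma`, `delta`,
#'   `gamma`, `hard` appended.
#' @export
derive_trial_values <- function(trials, params, immediate = 20, sigma_on_cup = TRUE) {
  check_td_trials(trials)
  stopifnot(inherits(params, "discount_params"))
  td <- trials$trial_type == "TD"
  if (!any(td)) stop("no TD trials in dataset")
  n <- nrow(trials)
  sv <- sv_star <- pi_ <- sigma <- delta <- gamma <- rep(NA_real_, n)
  hard <- rep(NA, n)
  is_apple <- trials$prime[td] == "apple"
  sv[td] <- subjective_value(trials$amount[td], trials$delay[td], params$k)
  sv_star[td] <- primed_subjective_value(trials$amount[td], trials$delay[td],
                                         params$k, params$a, is_apple)
  pi_[td] <- sv_star[td] - sv[td]
  sigma[td] <- params$a * sv_star[td]
  if (!sigma_on_cup) sigma[td][!is_apple] <- 0
  delta[td] <- sv[td] - immediate
  gamma[td] <- difficulty_index(delta[td], params$omega)
  hard[td] <- label_difficulty(gamma[td])
  cbind(trials, sv = sv, sv_star = sv_star, pi = pi_, sigma = sigma,
        delta = delta, gamma = gamma, hard = hard)
}

#' Median split of the difficulty index
#'
#' A trial is "hard" iff its difficulty index strictly exceeds the subject's
#' median index; ties at the median are labelled easy.
#'
#' @param gamma Numeric vector of per-trial difficulty indices (>= 2 values).
#' @return Logical vector: `TRUE` = hard.
#' @export
label_difficulty <- function(gamma) {
  if (length(gamma) < 2) stop("need at least 2 TD trials for a median split")
  if (anyNA(gamma)) stop("gamma contains missing values")
  gamma > stats::median(gamma)
}
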
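#' Session design configuration
#'
#' Defaults reproduce the scanning session structure: 6 delays x 6 amounts x
#' 3 repetitions x 2 primes = 216 temporal-discounting trials plus 108
#' perceptual-control trials, packed into 6 runs of 54 trials of 7000 ms
#' each (378 s of stimulation per run).
#'
#' @param delays Delays in days.
#' @param amounts_per_delay Number of delayed amounts per delay.
#' @param repetitions Presentations of each amount-delay-prime combination.
#' @param primes Prime conditions for TD trials.
#' @param n_runs Number of functional runs.
#' @param trials_per_run Trials per run.
#' @param trial_duration_ms Full trial length, ms.
#' @param n_pc_trials Number of perceptual-control trials in the session.
#' @param response_window_ms Response screen duration, ms.
#' @param amount_bounds Dollar envelope for calibrated amounts.
#' @param seed Integer seed controlling the (constrained) shuffle.
#' @return A list of class `design_config`.
#' @export
design_config <- function(delays = c(1, 10, 21, 55, 90, 180),
                          amounts_per_delay = 6,
                          repetitions = 3,
                          primes = c("apple", "cup"),
                          n_runs = 6,
                          trials_per_run = 54,
                          trial_duration_ms = 7000,
                          n_pc_trials = 108,
                          response_window_ms = 4000,
                          amount_bounds = c(20.10, 385.16),
                          seed = 1L) {
  n_td <- length(delays) * amounts_per_delay * repetitions * length(primes)
  if (n_td + n_pc_trials != n_runs * trials_per_run)
    stop(sprintf("trial counts do not pack: %d TD + %d PC != %d runs x %d",
                 n_td, n_pc_trials, n_runs, trials_per_run))
  if (n_pc_trials %% n_runs != 0)
    stop("PC trials must divide evenly across runs")
  structure(list(delays = delays, amounts_per_delay = amounts_per_delay,
                 repetitions = repetitions, primes = primes, n_runs = n_runs,
                 trials_per_run = trials_per_run,
                 trial_duration_ms = trial_duration_ms,
                 n_pc_trials = n_pc_trials,
                 response_window_ms = response_window_ms,
                 amount_bounds = amount_bounds, seed = as.integer(seed)),
            class = "design_config")
}

#' Calibrate delayed amounts to a pre-test discount rate
#'
#' For each delay `D` the grid places `n_amounts` amounts at fixed
#' choice-probability targets symmetric around 0.5 (octiles
#' `{1,2,3,5,6,7}/8` for the default 6), under the hyperbolic model at the
#' pre-test rate and a reference sensitivity: amount
#' `= (immediate + logit(p)/omega_ref) * (1 + k * D)`. By symmetry the
#' model-expected fraction of later choices over the grid is 0.5, the
#' balance the task calibration aims for. Amounts are rounded to cents and
#' clipped to `bounds` (clipping at short delays trades the exact symmetry
#' for positive, task-valid amounts).
#'
#' @param k_pretest Pre-test discount rate, 1/day (> 0).
#' @param delays Delays in days.
#' @param n_amounts Amounts per delay.
#' @param omega_ref Reference sensitivity used for spacing, 1/dollar.
#' @param immediate Immediate amount, dollars.
#' @param bounds Length-2 dollar envelope.
#' @return Matrix `length(delays) x n_amounts` of delayed amounts, rows
#'   named by delay.
#' @export
calibrate_amounts <- function(k_pretest, delays = c(1, 10, 21, 55, 90, 180),
                              n_amounts = 6, omega_ref = 0.3, immediate = 20,
                              bounds = c(20.10, 385.16)) {
  if (k_pretest <= 0) stop("k_pretest must be positive")
  p <- if (n_amounts == 6) c(1, 2, 3, 5, 6, 7) / 8 else
    seq_len(n_amounts) / (n_amounts + 1)
  off <- stats::qlogis(p) / omega_ref         # symmetric SV offsets
  grid <- matrix(NA_real_, length(delays), n_amounts)
  for (i in seq_along(delays)) {
    f <- 1 + k_pretest * delays[i]
    # shrink the offset scale where the envelope binds, keeping symmetry
    # (shrunk offsets still map to choice probabilities symmetric in 0.5)
    scale <- 1
    if ((immediate + min(off)) * f < bounds[1])
      scale <- min(scale, (bounds[1] / f - immediate) / min(off))
    if ((immediate + max(off)) * f > bounds[2])
      scale <- min(scale, (bounds[2] / f - immediate) / max(off))
    row <- round((immediate + off * scale) * f, 2)
    # cent rounding can tie neighbours at very shallow discounting; enforce
    # a one-cent minimum spacing (keeps amounts distinct and ordered)
    for (j in 2:n_amounts) if (row[j] <= row[j - 1]) row[j] <- row[j - 1] + 0.01
    grid[i, ] <- row
  }
  if (any(grid <= 0)) stop("calibrated amounts must be positive")
  dimnames(grid) <- list(delay = delays, NULL)
  grid
}

## Assign `repetitions` copies of each cell to distinct runs while keeping
## per-run TD counts exact: greedy fill preferring runs with most remaining
## capacity, random tie-break.
assign_runs <- function(n_cells, repetitions, n_runs, capacity) {
  stopifnot(n_cells * repetitions == n_runs * capacity)
  left <- rep(capacity, n_runs)
  out <- matrix(NA_integer_, n_cells, repetitions)
  for (i in sample.int(n_cells)) {
    avail <- order(-left + stats::runif(n_runs) * 0.5)  # capacity-major, random ties
    pick <- avail[seq_len(repetitions)]
    if (any(left[pick] == 0)) stop("run packing infeasible")
    out[i, ] <- pick
    left[pick] <- left[pick] - 1L
  }
  out
}

#' Build the full session trial schedule
#'
#' Expands the design into one row per trial: every amount-delay-prime
#' combination appears exactly `repetitions` times in the session, spread
#' over distinct runs with per-run counts balanced to within one trial of
#' perfect balance; perceptual-control (PC) trials fill each run to
#' `trials_per_run`; the side of the later option (and of the red PC cross)
#' is counterbalanced 50/50. Trial order within run is shuffled. Onsets are
#' assigned on the fixed 7000-ms trial grid. Deterministic given
#' `config$seed`.
#'
#' @param config A [design_config()].
#' @param k_pretest Pre-test discount rate used by [calibrate_amounts()].
#' @param omega_ref Reference sensitivity for amount spacing.
#' @return Data frame of class `td_schedule` with columns `run`, `trial`,
#'   `onset` (s, within run), `duration` (s; stimulus-to-response span used
#'   for modelling), `trial_type`, `prime`, `amount`, `delay`,
#'   `side_of_later`.
#' @export
build_design <- function(config = design_config(), k_pretest = 0.024,
                         omega_ref = 0.3) {
  stopifnot(inherits(config, "design_config"))
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(config$seed)

  amounts <- calibrate_amounts(k_pretest, config$delays,
                               config$amounts_per_delay, omega_ref,
                               bounds = config$amount_bounds)
  cells <- expand.grid(delay_i = seq_along(config$delays),
                       amount_i = seq_len(config$amounts_per_delay),
                       prime = config$primes, stringsAsFactors = FALSE)
  n_cells <- nrow(cells)
  td_per_run <- n_cells * config$repetitions / config$n_runs
  if (td_per_run != round(td_per_run)) stop("TD trials do not divide across runs")
  # assign runs separately per prime so marginal prime counts are equal per run
  runs <- matrix(NA_integer_, n_cells, config$repetitions)
  for (pr in config$primes) {
    i <- which(cells$prime == pr)
    cap <- length(i) * config$repetitions / config$n_runs
    if (cap != round(cap)) stop("prime cells do not divide across runs")
    runs[i, ] <- assign_runs(length(i), config$repetitions, config$n_runs, cap)
  }

  td <- cells[rep(seq_len(n_cells), config$repetitions), ]
  td$run <- as.integer(runs)
  td$trial_type <- "TD"
  td$amount <- amounts[cbind(td$delay_i, td$amount_i)]
  td$delay <- config$delays[td$delay_i]

  pc_per_run <- config$n_pc_trials / config$n_runs
  pc <- data.frame(delay_i = NA_integer_, amount_i = NA_integer_,
                   prime = "control",
                   run = rep(seq_len(config$n_runs), each = pc_per_run),
                   trial_type = "PC", amount = NA_real_, delay = NA_real_)
  sched <- rbind(td[names(pc)], pc)

  # counterbalance sides within run and trial type
  sched$side_of_later <- NA_character_
  for (r in seq_len(config$n_runs)) for (tt in c("TD", "PC")) {
    i <- which(sched$run == r & sched$trial_type == tt)
    sides <- rep(c("left", "right"), length.out = length(i))
    sched$side_of_later[i] <- sample(sides)
  }

  # shuffle order within run, assign onsets on the trial grid
  sched <- sched[order(sched$run, sample.int(nrow(sched))), ]
  sched$trial <- stats::ave(seq_len(nrow(sched)), sched$run, FUN = seq_along)
  trial_s <- config$trial_duration_ms / 1000
  sched$onset <- (sched$trial - 1) * trial_s
  tl <- trial_timeline(config)
  sched$onset_model <- sched$onset + tl$model_onset_s
  sched$duration <- tl$model_duration_s
  rownames(sched) <- NULL
  out <- sched[c("run", "trial", "onset", "onset_model", "duration",
                 "trial_type", "prime", "amount", "delay", "side_of_later")]
  attr(out, "config") <- config
  class(out) <- c("td_schedule", "data.frame")
  out
}

#' Within-trial component timeline
#'
#' Fixed component order and durations (ms): fixation 2417, pre-mask 84,
#' blank 16, prime (or blank on PC trials) 16, blank 16, post-mask 400,
#' response screen 4000; the 51-ms shortfall to the 7000-ms trial grid is
#' absorbed as terminal fixation padding. The modelled trial span starts at
#' mask onset (fixation end) and covers 4500 ms (visual presentation through
#' the response period).
#'
#' @param config A [design_config()].
#' @return List with `components` (named ms durations incl. terminal `pad`),
#'   `onsets_ms` (component onsets within trial), `model_onset_s`,
#'   `model_duration_s`, and `run_stimulus_s`.
#' @export
trial_timeline <- function(config = design_config()) {
  comp <- c(fixation = 2417, pre_mask = 84, blank1 = 16, prime = 16,
            blank2 = 16, post_mask = 400, response = config$response_window_ms)
  if (sum(comp) > config$trial_duration_ms)
    stop("trial components exceed trial duration")
  comp <- c(comp, pad = config$trial_duration_ms - sum(comp))
  onsets <- cumsum(c(0, comp[-length(comp)]))
  names(onsets) <- names(comp)
  list(components = comp, onsets_ms = onsets,
       model_onset_s = onsets[["pre_mask"]] / 1000,
       model_duration_s = 4.5,
       run_stimulus_s = config$trials_per_run * config$trial_duration_ms / 1000)
}

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
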
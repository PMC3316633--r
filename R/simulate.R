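#' Population specification for synthetic participants
#'
#' Defaults emulate the study group moments: 13 participants, discount rate
#' k ~ 0.024 +/- 0.018, premium a ~ 0.06 +/- 0.31 and sensitivity omega
#' ~ 0.3 +/- 0.1, truncated so that k > 0, k + a > 0 and omega > 0
#' (rejection sampling).
#'
#' @param n_subjects Number of participants.
#' @param k_mean,k_sd Discount-rate moments (1/day).
#' @param a_mean,a_sd Premium moments (1/day).
#' @param omega_mean,omega_sd Sensitivity moments (1/dollar).
#' @param seed Integer seed.
#' @return List of class `population_spec`.
#' @export
population_spec <- function(n_subjects = 13, k_mean = 0.024, k_sd = 0.018,
                            a_mean = 0.06, a_sd = 0.31,
                            omega_mean = 0.3, omega_sd = 0.1, seed = 1L) {
  structure(list(n_subjects = n_subjects, k_mean = k_mean, k_sd = k_sd,
                 a_mean = a_mean, a_sd = a_sd, omega_mean = omega_mean,
                 omega_sd = omega_sd, seed = as.integer(seed)),
            class = "population_spec")
}

#' Draw synthetic participants
#'
#' Truncated-normal draws honouring k > 0, k + a > 0, omega > 0.
#' Deterministic under `spec$seed`.
#'
#' @param spec A [population_spec()].
#' @return List of [discount_params] objects, length `spec$n_subjects`.
#' @export
sample_participants <- function(spec = population_spec()) {
  stopifnot(inherits(spec, "population_spec"))
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(spec$seed)
  draw <- function() {
    for (i in seq_len(10000)) {
      k <- stats::rnorm(1, spec$k_mean, spec$k_sd)
      a <- stats::rnorm(1, spec$a_mean, spec$a_sd)
      w <- stats::rnorm(1, spec$omega_mean, spec$omega_sd)
      if (k > 0 && k + a > 0 && w > 0) return(discount_params(k, a, w))
    }
    stop("truncation region infeasible: no valid draw in 10000 attempts")
  }
  lapply(seq_len(spec$n_subjects), function(i) draw())
}

#' Simulate choices on a trial schedule
#'
#' TD choices are Bernoulli draws with
#' `P(later) = logistic(omega * (SV* - immediate))` under the generative
#' premium model; PC trials are answered correctly with probability
#' `pc_accuracy` (nuisance). Deterministic under `seed`.
#'
#' @param params Generating [discount_params].
#' @param schedule A `td_schedule` from [build_design()].
#' @param seed Integer seed.
#' @param immediate Immediate amount, dollars.
#' @param pc_accuracy Probability of a correct PC response.
#' @return The schedule with `choice` ("now"/"later" on TD trials,
#'   "correct"/"error" on PC trials) appended.
#' @export
simulate_choices <- function(params, schedule, seed = 1L, immediate = 20,
                             pc_accuracy = 0.98) {
  stopifnot(inherits(params, "discount_params"))
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(seed)
  td <- schedule$trial_type == "TD"
  sv <- primed_subjective_value(schedule$amount[td], schedule$delay[td],
                                params$k, params$a, schedule$prime[td] == "apple")
  p <- choice_probability(sv, params$omega, immediate)
  choice <- rep(NA_character_, nrow(schedule))
  choice[td] <- ifelse(stats::runif(sum(td)) < p, "later", "now")
  choice[!td] <- ifelse(stats::runif(sum(!td)) < pc_accuracy, "correct", "error")
  out <- cbind(as.data.frame(schedule), choice = choice)
  attr(out, "config") <- attr(schedule, "config")
  attr(out, "true_params") <- params
  class(out) <- c("td_schedule", "data.frame")
  out
}

#' Simulate visibility-test responses
#'
#' Equal-variance Gaussian observer with sensitivity `d_prime_true` and
#' unbiased criterion (`c = d'/2`). For the detection test half of the
#' trials carry a masked image (signal) and half do not; the response is
#' "yes"/"no". For the identification test one of four images appears on
#' every trial and the modelled dichotomy is Apple versus the rest (one
#' quarter of trials are Apple-signal trials), response "apple"/"other".
#'
#' @param d_prime_true True sensitivity.
#' @param n_trials Even number of trials.
#' @param test `"detection"` or `"identification"`.
#' @param seed Integer seed.
#' @return Data frame `trial`, `signal` (logical), `response` with
#'   attribute `test`.
#' @export
simulate_visibility <- function(d_prime_true = 0, n_trials = 96,
                                test = c("detection", "identification"),
                                seed = 1L) {
  test <- match.arg(test)
  if (n_trials %% 2 != 0) stop("n_trials must be even")
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(seed)
  n_signal <- if (test == "detection") n_trials / 2 else n_trials / 4
  signal <- sample(rep(c(TRUE, FALSE), c(n_signal, n_trials - n_signal)))
  x <- stats::rnorm(n_trials, mean = ifelse(signal, d_prime_true, 0))
  yes <- x > d_prime_true / 2
  response <- if (test == "detection") ifelse(yes, "yes", "no") else
    ifelse(yes, "apple", "other")
  out <- data.frame(trial = seq_len(n_trials), signal = signal,
                    response = response)
  attr(out, "test") <- test
  out
}

#' BOLD simulation specification
#'
#' Grid, timing and noise parameters for the synthetic 4-D BOLD generator,
#' plus the planted ground-truth regions. The default grid (24 x 24 x 18
#' voxels at 4 mm) is a desk-scale stand-in for a whole-brain matrix; run
#' timing matches the acquisition (TR 2000 ms, 189 volumes per run, 6
#' runs). Effect types:
#' \describe{
#'   \item{sv_parametric / interaction_parametric / premium_parametric}{
#'     region amplitude scales trial-by-trial with SV, Sigma or Pi.}
#'   \item{prime_pattern / outcome_pattern / difficulty_pattern}{a fixed
#'     zero-sum (across region voxels) spatial pattern per class, so the
#'     regional mean signal is class-independent: decodable multivoxel
#'     structure without a univariate regional mean difference.}
#' }
#'
#' @param grid Integer 3-vector of voxel counts.
#' @param voxel_size_mm Isotropic voxel size.
#' @param tr_ms Repetition time.
#' @param volumes_per_run Volumes acquired per run.
#' @param n_runs Number of runs.
#' @param noise_sd Std. dev. of AR(1) noise (signal units; baseline 100).
#' @param ar1_rho AR(1) coefficient.
#' @param drift_amplitude Amplitude of the slow cosine drift.
#' @param td_amplitude,pc_amplitude Mean evoked response per TD / PC trial.
#' @param pattern_amplitude Per-voxel sd of planted class patterns.
#' @param parametric_scale Signal units per dollar of modulator.
#' @param regions Named list; each element `list(voxels = n x 3 integer
#'   matrix, effect = <type>, size = <multiplier>)`.
#' @return List of class `bold_spec`.
#' @export
bold_spec <- function(grid = c(24, 24, 18), voxel_size_mm = 4, tr_ms = 2000,
                      volumes_per_run = 189, n_runs = 6, noise_sd = 1,
                      ar1_rho = 0.3, drift_amplitude = 2,
                      td_amplitude = 1, pc_amplitude = 0.5,
                      pattern_amplitude = 0.5, parametric_scale = 0.02,
                      regions = list()) {
  for (nm in names(regions)) {
    v <- regions[[nm]]$voxels
    if (!is.matrix(v) || ncol(v) != 3) stop("region voxels must be an n x 3 matrix")
    if (any(v < 1) || any(sweep(v, 2, grid, ">")))
      stop("region '", nm, "' lies outside the grid")
  }
  if (length(regions) > 1) {
    keys <- unlist(lapply(regions, function(r)
      r$voxels[, 1] + (r$voxels[, 2] - 1) * 10^4 + (r$voxels[, 3] - 1) * 10^8))
    if (anyDuplicated(keys)) stop("planted regions must be disjoint")
  }
  structure(list(grid = as.integer(grid), voxel_size_mm = voxel_size_mm,
                 tr_ms = tr_ms, volumes_per_run = volumes_per_run,
                 n_runs = n_runs, noise_sd = noise_sd, ar1_rho = ar1_rho,
                 drift_amplitude = drift_amplitude,
                 td_amplitude = td_amplitude, pc_amplitude = pc_amplitude,
                 pattern_amplitude = pattern_amplitude,
                 parametric_scale = parametric_scale, regions = regions),
            class = "bold_spec")
}

#' Rectangular planted region helper
#'
#' @param x,y,z Integer index ranges.
#' @param effect Effect type (see [bold_spec()]).
#' @param size Effect-size multiplier.
#' @export
region_box <- function(x, y, z, effect, size = 1) {
  list(voxels = as.matrix(expand.grid(x = x, y = y, z = z)),
       effect = effect, size = size)
}

voxel_index <- function(voxels, grid) {
  (voxels[, 3] - 1) * grid[1] * grid[2] + (voxels[, 2] - 1) * grid[1] + voxels[, 1]
}

## sampled event regressor on the volume grid: boxcar convolved with the
## canonical double-gamma response, oversampled then decimated
event_regressor <- function(onsets, durations, amplitudes, n_vols, tr_s,
                            oversampling = 10) {
  dt <- tr_s / oversampling
  n_fine <- n_vols * oversampling
  x <- numeric(n_fine)
  for (i in seq_along(onsets)) {
    j0 <- floor(onsets[i] / dt) + 1
    j1 <- min(n_fine, ceiling((onsets[i] + durations[i]) / dt))
    if (j0 <= n_fine) x[j0:min(j1, n_fine)] <- x[j0:min(j1, n_fine)] + amplitudes[i]
  }
  h <- hrf_kernel(dt * 1000)
  h <- h / sum(h)   # unit mass: a sustained event of amplitude A plateaus at A
  conv <- stats::convolve(x, rev(h), type = "open")[seq_len(n_fine)]
  conv[seq(1, n_fine, by = oversampling)]
}

#' Simulate a 4-D BOLD series with planted ground truth
#'
#' Forward model: per run, each condition's events (duration = the modelled
#' 4500-ms trial span, onsets from the schedule) are convolved with the
#' canonical double-gamma response. Every in-brain voxel receives baseline
#' 100, the mean TD/PC evoked response — with voxel-specific haemodynamic
#' gain (uniform 0.5-1.5) and latency (uniform over -1..+1 s in 0.5-s
#' steps), emulating the regional variability of the vascular response —
#' plus cosine drift and AR(1) Gaussian noise. Planted regions add, on top: parametric effects whose amplitude
#' scales trial-by-trial with the generative SV, Sigma or Pi (mean-centred),
#' or class patterns — a fixed spatial pattern per class (apple/cup,
#' now/later, easy/hard), zero-sum across region voxels and drawn fresh per
#' subject (seed), so classes are decodable from the multivoxel pattern but
#' the regional mean does not differ.
#'
#' @param schedule Schedule with simulated choices ([simulate_choices()]).
#' @param params Generating [discount_params] (used for SV/Sigma/Pi and the
#'   difficulty median split).
#' @param spec A [bold_spec()].
#' @param seed Integer seed (noise and subject-specific patterns).
#' @return List of class `bold_series`: `data` (4-D array x,y,z,time with
#'   runs concatenated), `spec`, `mask` (logical 3-D array), `truth`
#'   (per-region voxel indices and patterns).
#' @export
simulate_bold <- function(schedule, params, spec = bold_spec(), seed = 1L) {
  stopifnot(inherits(spec, "bold_spec"))
  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(seed)
  grid <- spec$grid
  n_vox <- prod(grid)
  tr_s <- spec$tr_ms / 1000
  nv <- spec$volumes_per_run
  n_t <- nv * spec$n_runs
  der <- derive_trial_values(schedule, params)
  der$later <- der$choice == "later"

  ## voxel-wise haemodynamic heterogeneity for the evoked response
  hrf_delays_s <- seq(-1, 1, by = 0.5)
  vox_delay <- sample.int(length(hrf_delays_s), n_vox, replace = TRUE)
  vox_gain <- stats::runif(n_vox, 0.5, 1.5)

  ## per-run condition regressors and planted-effect time courses
  Y <- matrix(0, n_t, n_vox)           # time x voxel, signal then noise added
  truth <- list()
  region_idx <- lapply(spec$regions, function(r) voxel_index(r$voxels, grid))
  patterns <- list()
  for (nm in names(spec$regions)) {
    r <- spec$regions[[nm]]
    if (grepl("_pattern$", r$effect)) {
      nvx <- nrow(r$voxels)
      pat <- replicate(2, {
        p <- stats::rnorm(nvx)
        p - mean(p)                     # zero-sum across region voxels
      })
      patterns[[nm]] <- pat * spec$pattern_amplitude * r$size
    }
  }

  for (run in seq_len(spec$n_runs)) {
    rows <- which(der$run == run)
    d <- der[rows, ]
    t0 <- (run - 1) * nv
    idx_t <- t0 + seq_len(nv)
    reg <- function(sel, amp) {
      if (!any(sel) || all(amp[sel] == 0)) return(numeric(nv))
      event_regressor(d$onset_model[sel], d$duration[sel], amp[sel], nv, tr_s)
    }
    td <- d$trial_type == "TD"
    for (dl in seq_along(hrf_delays_s)) {
      sel_v <- which(vox_delay == dl)
      if (!length(sel_v)) next
      sh <- hrf_delays_s[dl]
      on_sh <- pmax(d$onset_model + sh, 0)
      base_sig <-
        (if (any(td)) event_regressor(on_sh[td], d$duration[td],
           rep(spec$td_amplitude, sum(td)), nv, tr_s) else 0) +
        (if (any(!td)) event_regressor(on_sh[!td], d$duration[!td],
           rep(spec$pc_amplitude, sum(!td)), nv, tr_s) else 0)
      Y[idx_t, sel_v] <- Y[idx_t, sel_v] + base_sig %o% vox_gain[sel_v]
    }

    for (nm in names(spec$regions)) {
      r <- spec$regions[[nm]]
      vi <- region_idx[[nm]]
      if (grepl("_parametric$", r$effect)) {
        mod <- switch(r$effect,
                      sv_parametric = d$sv,
                      interaction_parametric = d$sigma,
                      premium_parametric = d$pi)
        amp <- ifelse(td, mod - mean(mod[td]), 0) * spec$parametric_scale * r$size
        amp[is.na(amp)] <- 0
        Y[idx_t, vi] <- Y[idx_t, vi] + reg(td, amp)
      } else {
        classes <- switch(r$effect,
                          prime_pattern = list(td & d$prime == "apple",
                                               td & d$prime == "cup"),
                          outcome_pattern = list(td & d$later %in% TRUE,
                                                 td & d$later %in% FALSE),
                          difficulty_pattern = list(td & d$hard %in% TRUE,
                                                    td & d$hard %in% FALSE))
        for (ci in 1:2) {
          tc <- reg(classes[[ci]], rep(1, nrow(d)))
          if (all(tc == 0)) next
          Y[idx_t, vi] <- Y[idx_t, vi] + tc %o% patterns[[nm]][, ci]
        }
      }
    }
    ## cosine drift + AR(1) noise, per run
    drift <- spec$drift_amplitude *
      cos(pi * (seq_len(nv) - 0.5) / nv) %o% stats::runif(n_vox, 0.5, 1)
    eps <- matrix(stats::rnorm(nv * n_vox, sd = spec$noise_sd), nv, n_vox)
    if (spec$ar1_rho != 0 && spec$noise_sd > 0) {
      for (t in 2:nv) eps[t, ] <- eps[t, ] + spec$ar1_rho * eps[t - 1, ]
    }
    Y[idx_t, ] <- Y[idx_t, ] + 100 + drift + eps
  }

  mask <- array(TRUE, grid)
  truth <- lapply(names(spec$regions), function(nm)
    list(name = nm, effect = spec$regions[[nm]]$effect,
         voxels = spec$regions[[nm]]$voxels, index = region_idx[[nm]],
         pattern = patterns[[nm]]))
  names(truth) <- names(spec$regions)
  structure(list(data = array(t(Y), c(grid, n_t)), spec = spec, mask = mask,
                 truth = truth),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  g <- x$spec$grid
  cat(sprintf("bold_series: %d x %d x %d voxels, %d runs x %d volumes (TR %g s)\n",
              g[1], g[2], g[3], x$spec$n_runs, x$spec$volumes_per_run,
              x$spec$tr_ms / 1000))
  if (length(x$truth))
    cat("planted:", paste(sprintf("%s [%s]", names(x$truth),
        vapply(x$truth, function(t) t$effect, "")), collapse = ", "), "\n")
  invisible(x)
}
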
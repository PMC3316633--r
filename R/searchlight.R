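#' Lattice offsets of a voxel sphere
#'
#' All integer offsets with Euclidean norm <= `radius`, centre included
#' (7 offsets at radius 1, 33 at radius 2, 123 at radius 3).
#'
#' @param radius Sphere radius in voxels (>= 1).
#' @return Integer matrix, one offset per row.
#' @export
sphere_offsets <- function(radius = 3) {
  if (radius < 1) stop("radius must be at least 1")
  r <- floor(radius)
  g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
  keep <- g$x^2 + g$y^2 + g$z^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

label_clusters <- function(supra) {
  .label_clusters_cpp(as.logical(supra), dim(supra))
}

max_cluster_size <- function(supra) {
  .max_cluster_size_cpp(as.logical(supra), dim(supra))
}

#' Finite impulse response estimates per condition, bin and run
#'
#' Estimates the evoked response shape without assuming a haemodynamic
#' model: each trial is subdivided into `n_bins` bins of `bin_width_ms`
#' (default 6 x 2000 ms = one TR each, covering 12 s from the volume at
#' stimulus onset) and each condition x bin gets one stick parameter per
#' run (2 x 6 = 12 condition regressors per run for a two-class labelling),
#' estimated by per-run least squares alongside a 128-s high-pass drift
#' set. Runs with fewer than `min_trials` trials of either class are
#' excluded; if fewer than 3 usable runs remain the subject is excluded
#' (condition `td_subject_excluded`).
#'
#' @param bold A `bold_series`.
#' @param schedule Schedule with choices.
#' @param labels Character/logical vector over schedule rows giving the
#'   two-class labelling of TD trials (`NA` = trial not used). The first
#'   level in sort order is class 1.
#' @param n_bins,bin_width_ms FIR bin structure.
#' @param min_trials Per-run minimum trials per class.
#' @param cutoff_s High-pass cut-off.
#' @return List of class `td_fir`: `estimates` (array voxel x class x bin
#'   x run), `classes`, `runs_used`, `n_bins`, `grid`.
#' @export
fit_fir <- function(bold, schedule, labels, n_bins = 6, bin_width_ms = 2000,
                    min_trials = 4, cutoff_s = 128) {
  stopifnot(inherits(bold, "bold_series"))
  spec <- bold$spec
  if (bin_width_ms != spec$tr_ms)
    stop("FIR bins must equal one TR in this implementation")
  if (is.logical(labels)) labels <- ifelse(labels, "yes", "no")
  classes <- sort(unique(stats::na.omit(labels)))
  if (length(classes) != 2) stop("labels must define exactly two classes")
  nv <- spec$volumes_per_run
  n_vox <- prod(spec$grid)
  Ymat <- matrix(bold$data, n_vox, nv * spec$n_runs)

  runs_used <- integer(0)
  est <- list()
  for (run in seq_len(spec$n_runs)) {
    in_run <- schedule$run == run
    lab <- labels[in_run]
    d <- schedule[in_run, ]
    counts <- table(factor(lab, levels = classes))
    if (any(counts < min_trials)) next
    X <- matrix(0, nv, 2 * n_bins)
    colnames(X) <- paste0(rep(classes, each = n_bins), "_bin", seq_len(n_bins))
    onset_vol <- floor(d$onset_model / (spec$tr_ms / 1000)) + 1
    for (ci in 1:2) {
      tr_idx <- which(!is.na(lab) & lab == classes[ci])
      for (b in seq_len(n_bins)) {
        vols <- onset_vol[tr_idx] + (b - 1)
        vols <- vols[vols >= 1 & vols <= nv]
        col <- (ci - 1) * n_bins + b
        for (v in vols) X[v, col] <- X[v, col] + 1
      }
    }
    Xfull <- cbind(X, drift_basis(nv, spec$tr_ms / 1000, cutoff_s))
    Y <- t(Ymat[, (run - 1) * nv + seq_len(nv), drop = FALSE])
    b_hat <- qr.coef(qr(Xfull), Y)[seq_len(2 * n_bins), , drop = FALSE]
    runs_used <- c(runs_used, run)
    est[[length(est) + 1]] <- b_hat
  }
  if (length(runs_used) < 3) {
    cond <- structure(class = c("td_subject_excluded", "error", "condition"),
                      list(message = sprintf(
                        "subject excluded: only %d run(s) with >= %d trials per class",
                        length(runs_used), min_trials), call = NULL))
    stop(cond)
  }
  arr <- array(NA_real_, c(n_vox, 2, n_bins, length(runs_used)))
  for (r in seq_along(est)) {
    for (ci in 1:2) {
      rows <- (ci - 1) * n_bins + seq_len(n_bins)
      arr[, ci, , r] <- t(est[[r]][rows, , drop = FALSE])
    }
  }
  structure(list(estimates = arr, classes = classes, runs_used = runs_used,
                 n_bins = n_bins, grid = spec$grid,
                 voxel_size_mm = spec$voxel_size_mm),
            class = "td_fir")
}

#' Searchlight decoding of a two-class labelling
#'
#' For every centre voxel, pattern vectors are the per-run, per-class FIR
#' estimates over the voxels of a sphere of `radius` voxels (truncated at
#' grid edges); a linear soft-margin SVM (fixed regularization `C = 1`,
#' per-fold training-mean removal, no other scaling) is trained on all but
#' one run and tested on the held-out run's two vectors, cycling over runs;
#' accuracy averages folds and the analysed bins (default bins 5 and 6;
#' `combine = "concatenate"` stacks the bins into one vector instead).
#' Chance is 0.5 by construction (one vector per class per fold).
#'
#' @param fir A `td_fir`.
#' @param radius Sphere radius in voxels.
#' @param bins Analysed time bins.
#' @param mask Optional logical 3-D array.
#' @param combine `"average"` or `"concatenate"`.
#' @param cost SVM regularization constant.
#' @return List of class `td_accuracy_map`: `accuracy` (3-D array in
#'   \[0, 1\], NA outside mask), `chance` (0.5), `radius`, `n_folds`.
#' @export
searchlight_decode <- function(fir, radius = 3, bins = c(5, 6), mask = NULL,
                               combine = c("average", "concatenate"),
                               cost = 1) {
  stopifnot(inherits(fir, "td_fir"))
  combine <- match.arg(combine)
  if (any(bins < 1 | bins > fir$n_bins)) stop("analysed bins out of range")
  n_runs <- length(fir$runs_used)
  if (n_runs < 3) stop("need at least 3 usable runs")
  grid <- fir$grid
  if (is.null(mask)) mask <- array(TRUE, grid)
  acc <- .searchlight_cpp(as.numeric(fir$estimates), grid,
                          as.logical(mask), sphere_offsets(radius),
                          fir$n_bins, n_runs, as.integer(bins), cost,
                          combine == "concatenate")
  structure(list(accuracy = array(acc, grid), chance = 0.5, radius = radius,
                 bins = bins, n_folds = n_runs,
                 label_pair = fir$classes, voxel_size_mm = fir$voxel_size_mm),
            class = "td_accuracy_map")
}

#' @export
print.td_accuracy_map <- function(x, ...) {
  cat(sprintf("searchlight accuracy map (%s vs %s): radius %d, %d folds, mean %.3f\n",
              x$label_pair[1], x$label_pair[2], x$radius, x$n_folds,
              mean(x$accuracy, na.rm = TRUE)))
  invisible(x)
}

#' Group inference on searchlight accuracy maps
#'
#' Smooths each subject's accuracy-minus-chance map (8 mm FWHM default) and
#' runs the one-sample sign-flip cluster-FWE test against zero (above-chance
#' decoding), via [group_cluster_fwe()].
#'
#' @param maps List of `td_accuracy_map` (>= 5 subjects, common grid).
#' @param fwhm_mm Smoothing kernel.
#' @param ... Passed to [group_cluster_fwe()].
#' @return A `td_cluster_result`.
#' @export
group_accuracy_inference <- function(maps, fwhm_mm = 8, ...) {
  arr <- lapply(maps, function(m) {
    a <- m$accuracy - m$chance
    a[is.na(a)] <- 0
    gaussian_smooth(a, fwhm_mm, m$voxel_size_mm)
  })
  group_cluster_fwe(arr, ...)
}

#' Decode decision difficulty within each prime condition
#'
#' Repeats FIR estimation and searchlight decoding of easy vs hard trials
#' separately on Apple-only and cup-only trial sets, with the median split
#' of the difficulty index recomputed within condition. Subjects with
#' unbalanced runs are excluded by the [fit_fir()] rule.
#'
#' @param bold A `bold_series`.
#' @param schedule Schedule with choices.
#' @param params Fitted [discount_params] for the difficulty index.
#' @param radius,bins Passed to [searchlight_decode()].
#' @param min_trials Passed to [fit_fir()].
#' @return Named list of `td_accuracy_map` (`apple`, `cup`).
#' @export
within_condition_difficulty_decode <- function(bold, schedule, params,
                                               radius = 3, bins = c(5, 6),
                                               min_trials = 4) {
  out <- list()
  for (pr in c("apple", "cup")) {
    sel <- schedule$trial_type == "TD" & schedule$prime == pr
    gamma <- rep(NA_real_, nrow(schedule))
    gamma[sel] <- difficulty_index(
      subjective_value(schedule$amount[sel], schedule$delay[sel], params$k) - 20,
      params$omega)
    labels <- rep(NA_character_, nrow(schedule))
    labels[sel] <- ifelse(label_difficulty(gamma[sel]), "hard", "easy")
    fir <- fit_fir(bold, schedule, labels, min_trials = min_trials)
    out[[pr]] <- searchlight_decode(fir, radius = radius, bins = bins)
  }
  out
}
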
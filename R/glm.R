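#' Canonical double-gamma haemodynamic response kernel
#'
#' Difference of two gamma densities with modes at 6 s (response peak) and
#' 16 s (undershoot), peak:undershoot ratio 6, sampled at `dt_ms` over 32 s
#' and normalized to unit peak.
#'
#' @param dt_ms Sampling interval in ms.
#' @param length_s Kernel support in seconds.
#' @return Numeric vector of kernel samples.
#' @export
hrf_kernel <- function(dt_ms, length_s = 32) {
  if (dt_ms <= 0) stop("dt_ms must be positive")
  t <- seq(0, length_s, by = dt_ms / 1000)
  h <- stats::dgamma(t, shape = 7, scale = 1) -
    stats::dgamma(t, shape = 17, scale = 1) / 6
  h / max(h)
}

## cosine (DCT-II) drift basis implementing a high-pass cut-off, plus intercept
drift_basis <- function(n_vols, tr_s, cutoff_s = 128) {
  k_max <- max(0, floor(2 * n_vols * tr_s / cutoff_s))
  t <- seq_len(n_vols) - 0.5
  X <- cbind(intercept = rep(1, n_vols))
  for (k in seq_len(k_max))
    X <- cbind(X, cos(pi * k * t / n_vols))
  colnames(X) <- c("intercept", if (k_max > 0) paste0("drift", seq_len(k_max)))
  X
}

## residualize column y against columns X (serial orthogonalization step)
orth_against <- function(y, X) {
  y - X %*% qr.coef(qr(X), y)
}

build_design_runs <- function(schedule, conditions, modulators, spec,
                              cutoff_s = 128) {
  tr_s <- spec$tr_ms / 1000
  nv <- spec$volumes_per_run
  runs <- vector("list", spec$n_runs)
  for (run in seq_len(spec$n_runs)) {
    d <- schedule[schedule$run == run, ]
    cols <- list()
    for (nm in names(conditions)) {
      sel <- conditions[[nm]](d)
      cols[[nm]] <- if (any(sel))
        event_regressor(d$onset_model[sel], d$duration[sel],
                        rep(1, sum(sel)), nv, tr_s) else numeric(nv)
    }
    cond_mat <- do.call(cbind, cols)
    mod_mat <- NULL
    for (nm in names(modulators)) {
      m <- modulators[[nm]](d)           # list(sel, value)
      sel <- m$sel
      val <- m$value[sel]
      val <- val - mean(val)             # mean-centred over carrying trials
      col <- event_regressor(d$onset_model[sel], d$duration[sel], val, nv, tr_s)
      # serial orthogonalization: conditions first, then earlier modulators
      basis <- cbind(cond_mat, mod_mat)
      col <- orth_against(col, basis)
      mod_mat <- cbind(mod_mat, col)
      colnames(mod_mat)[ncol(mod_mat)] <- nm
    }
    X <- cbind(cond_mat, mod_mat, drift_basis(nv, tr_s, cutoff_s))
    runs[[run]] <- X
  }
  zero_cols <- colnames(runs[[1]])[vapply(colnames(runs[[1]]), function(cn)
    all(vapply(runs, function(X) all(abs(X[, cn]) < 1e-12), logical(1))),
    logical(1))]
  if (length(zero_cols)) {
    warning("dropping all-zero design column(s): ", paste(zero_cols, collapse = ", "))
    runs <- lapply(runs, function(X) X[, setdiff(colnames(X), zero_cols), drop = FALSE])
  }
  structure(list(runs = runs, columns = colnames(runs[[1]]), spec = spec),
            class = "td_design_matrix")
}

#' Design matrix for the priming interaction model
#'
#' Condition boxcars (4500-ms modelled span) for apple, cup and control
#' trials; TD trials additionally carry two mean-centred parametric
#' modulators, in order SV then Sigma (= a * SV*, the prime-by-value
#' interaction), the second serially orthogonalized against the conditions
#' and the first. `reverse_order = TRUE` enters Sigma first (used to factor
#' the interaction out and test prime-independent SV encoding). Cosine
#' drift regressors implement a 128-s high-pass per run.
#'
#' @param schedule Schedule with choices.
#' @param params Fitted [discount_params] for the subject.
#' @param spec The [bold_spec()] the volumes were generated/acquired with.
#' @param reverse_order Enter the interaction modulator before SV.
#' @param sigma_on_cup Passed to [derive_trial_values()].
#' @return A `td_design_matrix` (per-run matrices sharing column names).
#' @export
build_interaction_design <- function(schedule, params, spec,
                                     reverse_order = FALSE,
                                     sigma_on_cup = TRUE) {
  der <- derive_trial_values(schedule, params, sigma_on_cup = sigma_on_cup)
  conditions <- list(
    apple = function(d) d$trial_type == "TD" & d$prime == "apple",
    cup = function(d) d$trial_type == "TD" & d$prime == "cup",
    control = function(d) d$trial_type == "PC")
  mods <- list(
    sv = function(d) list(sel = d$trial_type == "TD", value = d$sv),
    sigma = function(d) list(sel = d$trial_type == "TD", value = d$sigma))
  if (all(abs(der$sigma[der$trial_type == "TD"]) < 1e-12)) {
    warning("interaction modulator is identically zero (a = 0); dropped")
    mods$sigma <- NULL
  }
  if (reverse_order) mods <- rev(mods)
  build_design_runs(der, conditions, mods, spec)
}

#' Design matrix for the priming premium model
#'
#' SV enters as a mean-centred modulator of no interest on all TD trials;
#' the premium Pi (= SV* - SV) enters on Apple trials only, orthogonalized
#' against SV. `correct_only = TRUE` restricts the premium modulator to
#' trials whose observed choice matches the model prediction (requires a
#' fitted model via `fit`).
#'
#' @inheritParams build_interaction_design
#' @param correct_only Restrict the premium modulator to correctly
#'   predicted trials.
#' @param fit Optional `td_fit` used for the prediction restriction.
#' @export
build_premium_design <- function(schedule, params, spec, correct_only = FALSE,
                                 fit = NULL) {
  der <- derive_trial_values(schedule, params)
  keep <- rep(TRUE, nrow(der))
  if (correct_only) {
    if (is.null(fit)) stop("correct_only requires a fitted model")
    pred <- predict_choices(fit, der)
    keep <- pred$correct %in% TRUE
  }
  der$premium_keep <- keep
  conditions <- list(
    apple = function(d) d$trial_type == "TD" & d$prime == "apple",
    cup = function(d) d$trial_type == "TD" & d$prime == "cup",
    control = function(d) d$trial_type == "PC")
  mods <- list(
    sv = function(d) list(sel = d$trial_type == "TD", value = d$sv),
    pi = function(d) list(sel = d$trial_type == "TD" & d$prime == "apple" &
                            d$premium_keep,
                          value = d$pi))
  if (all(abs(der$pi[der$trial_type == "TD" & der$prime == "apple"]) < 1e-12)) {
    warning("premium modulator is identically zero (a = 0); dropped")
    mods$pi <- NULL
  }
  build_design_runs(der, conditions, mods, spec)
}

#' Fit a run-wise ordinary least squares GLM
#'
#' Per-run OLS of every voxel's time series on the run's design matrix
#' (drift columns implement the high-pass); betas averaged across runs.
#' Errors on rank-deficient designs, naming the offending columns.
#'
#' @param bold A `bold_series`.
#' @param design A `td_design_matrix` with matching run structure.
#' @return List of class `td_glm_fit`: `beta` (matrix columns x voxels,
#'   run-averaged), `sigma2` (mean residual variance per voxel), `columns`,
#'   `grid`, `df_resid`.
#' @export
fit_glm <- function(bold, design) {
  stopifnot(inherits(bold, "bold_series"), inherits(design, "td_design_matrix"))
  grid <- bold$spec$grid
  n_vox <- prod(grid)
  nv <- bold$spec$volumes_per_run
  n_runs <- bold$spec$n_runs
  if (length(design$runs) != n_runs) stop("design and volumes disagree on run count")
  Ymat <- matrix(bold$data, n_vox, nv * n_runs)
  p <- length(design$columns)
  beta_sum <- matrix(0, p, n_vox)
  rss <- numeric(n_vox)
  df <- 0
  for (run in seq_len(n_runs)) {
    X <- design$runs[[run]]
    if (nrow(X) != nv) stop("design rows != volumes in run ", run)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      stop("rank-deficient design in run ", run, "; collinear columns: ",
           paste(bad, collapse = ", "))
    }
    Y <- t(Ymat[, (run - 1) * nv + seq_len(nv), drop = FALSE])
    b <- qr.coef(qrX, Y)
    beta_sum <- beta_sum + b
    res <- Y - X %*% b
    rss <- rss + colSums(res^2)
    df <- df + nv - ncol(X)
  }
  structure(list(beta = beta_sum / n_runs, sigma2 = rss / df,
                 columns = design$columns, grid = grid, df_resid = df),
            class = "td_glm_fit")
}

#' Contrast effect map from a GLM fit
#'
#' @param fit A `td_glm_fit`.
#' @param weights Named numeric vector of contrast weights over design
#'   columns (unnamed columns get 0).
#' @return 3-D array of contrast effects (run-averaged betas combined).
#' @export
contrast_map <- function(fit, weights) {
  stopifnot(inherits(fit, "td_glm_fit"))
  w <- stats::setNames(numeric(length(fit$columns)), fit$columns)
  unknown <- setdiff(names(weights), fit$columns)
  if (length(unknown)) stop("unknown design columns: ", paste(unknown, collapse = ", "))
  w[names(weights)] <- weights
  array(drop(crossprod(fit$beta, w)), fit$grid)
}

#' Separable Gaussian smoothing of a 3-D map
#'
#' Truncated Gaussian kernel applied along each axis; weights renormalized
#' at the volume edges.
#'
#' @param arr 3-D array.
#' @param fwhm_mm Full width at half maximum in mm (0 = no smoothing).
#' @param voxel_mm Isotropic voxel size in mm.
#' @export
gaussian_smooth <- function(arr, fwhm_mm = 8, voxel_mm = 4) {
  if (fwhm_mm <= 0) return(arr)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  half <- max(1, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  sm <- function(a, dim_i) {
    out <- array(0, dim(a)); wt <- array(0, dim(a))
    n <- dim(a)[dim_i]
    for (j in seq_along(kern)) {
      off <- j - half - 1
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      idx_to <- which(ok); idx_from <- src[ok]
      if (dim_i == 1) {
        out[idx_to, , ] <- out[idx_to, , ] + kern[j] * a[idx_from, , ]
        wt[idx_to, , ] <- wt[idx_to, , ] + kern[j]
      } else if (dim_i == 2) {
        out[, idx_to, ] <- out[, idx_to, ] + kern[j] * a[, idx_from, ]
        wt[, idx_to, ] <- wt[, idx_to, ] + kern[j]
      } else {
        out[, , idx_to] <- out[, , idx_to] + kern[j] * a[, , idx_from]
        wt[, , idx_to] <- wt[, , idx_to] + kern[j]
      }
    }
    out / wt
  }
  sm(sm(sm(arr, 1), 2), 3)
}

group_z_map <- function(M) {
  # M: subjects x voxels; one-sample t converted to Z
  n <- nrow(M)
  m <- colMeans(M)
  v <- (colSums(M^2) - n * m^2) / (n - 1)
  t_stat <- m / sqrt(pmax(v, 1e-300) / n)
  sign(t_stat) * abs(stats::qnorm(stats::pt(-abs(t_stat), df = n - 1,
                                            log.p = TRUE), log.p = TRUE))
}

#' Group cluster-level FWE inference by sign-flip permutation
#'
#' One-sample group t over subject maps, converted to Z; clusters formed at
#' `Z > z_thresh` under 6-connectivity; the family-wise null distribution
#' of the maximum cluster size is built by randomly sign-flipping subject
#' maps (exchangeable under the null of zero mean); clusters larger than
#' the 95th percentile of the null are significant. `tails = "both"`
#' clusters `|Z| > z_thresh` instead.
#'
#' @param maps List of per-subject 3-D arrays on a common grid (>= 5).
#' @param mask Logical 3-D array (default all voxels).
#' @param z_thresh Cluster-forming threshold.
#' @param n_perm Number of sign-flip permutations (>= 100).
#' @param seed Integer seed.
#' @param alpha Cluster-level FWE threshold.
#' @param tails `"positive"` or `"both"`.
#' @return List of class `td_cluster_result`: `clusters` (data frame:
#'   size, peak_z, peak_x/y/z, p_fwe), `z_map`, `critical_size`,
#'   `null_max_sizes`.
#' @export
group_cluster_fwe <- function(maps, mask = NULL, z_thresh = 1.96,
                              n_perm = 1000, seed = 1L, alpha = 0.05,
                              tails = c("positive", "both")) {
  tails <- match.arg(tails)
  if (length(maps) < 5) stop("need at least 5 subject maps")
  if (n_perm < 100) stop("n_perm must be at least 100")
  grid <- dim(maps[[1]])
  if (is.null(mask)) mask <- array(TRUE, grid)
  M <- do.call(rbind, lapply(maps, as.vector))
  if (!all(is.finite(M[, as.vector(mask)]))) stop("non-finite values inside mask")
  n <- nrow(M)
  keep <- as.vector(mask)
  thresholded <- function(z) {
    zm <- numeric(length(keep)); zm[keep] <- z
    supra <- if (tails == "both") abs(zm) > z_thresh else zm > z_thresh
    supra & keep
  }
  z_obs <- group_z_map(M[, keep, drop = FALSE])
  supra_obs <- thresholded(z_obs)
  labels <- label_clusters(array(supra_obs, grid))

  old <- .Random.seed.save(); on.exit(.Random.seed.restore(old))
  set.seed(seed)
  Mk <- M[, keep, drop = FALSE]
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    zb <- group_z_map(Mk * s)
    supra <- thresholded(zb)
    null_max[b] <- if (any(supra)) max_cluster_size(array(supra, grid)) else 0
  }
  crit <- stats::quantile(null_max, 1 - alpha, type = 1)

  cl_ids <- setdiff(unique(labels[labels > 0]), 0)
  zm_full <- numeric(length(keep)); zm_full[keep] <- z_obs
  rows <- lapply(cl_ids, function(id) {
    idx <- which(labels == id)
    size <- length(idx)
    zz <- if (tails == "both") abs(zm_full[idx]) else zm_full[idx]
    pk <- idx[which.max(zz)]
    co <- arrayInd(pk, grid)
    data.frame(size = size, peak_z = zm_full[pk], peak_x = co[1],
               peak_y = co[2], peak_z_coord = co[3],
               p_fwe = (1 + sum(null_max >= size)) / (n_perm + 1))
  })
  clusters <- if (length(rows)) do.call(rbind, rows) else
    data.frame(size = integer(), peak_z = numeric(), peak_x = integer(),
               peak_y = integer(), peak_z_coord = integer(), p_fwe = numeric())
  clusters <- clusters[order(-clusters$size), , drop = FALSE]
  significant <- clusters[clusters$size > crit, , drop = FALSE]
  structure(list(clusters = clusters, significant = significant,
                 z_map = array(zm_full, grid), critical_size = as.numeric(crit),
                 null_max_sizes = null_max, z_thresh = z_thresh,
                 alpha = alpha, labels = array(labels, grid)),
            class = "td_cluster_result")
}

#' @export
print.td_cluster_result <- function(x, ...) {
  cat(sprintf("cluster-FWE: %d supra-threshold cluster(s), %d significant (size > %.0f)\n",
              nrow(x$clusters), nrow(x$significant), x$critical_size))
  if (nrow(x$significant)) print(x$significant, row.names = FALSE)
  invisible(x)
}

#' Univariate apple-vs-cup condition contrast across subjects
#'
#' Fits the condition-boxcar GLM per subject, takes the apple - cup
#' contrast on the boxcar betas, smooths, and runs two-tailed cluster-FWE
#' inference — the non-parametric control analysis testing whether any
#' region differs in mean activation between prime conditions.
#'
#' @param bold_list,design_list Per-subject volumes and designs (the
#'   designs must contain `apple` and `cup` columns).
#' @param fwhm_mm Smoothing applied to subject contrast maps.
#' @param ... Passed to [group_cluster_fwe()].
#' @return A `td_cluster_result`.
#' @export
condition_contrast_null <- function(bold_list, design_list, fwhm_mm = 8, ...) {
  stopifnot(length(bold_list) == length(design_list))
  maps <- mapply(function(bold, design) {
    fit <- fit_glm(bold, design)
    gaussian_smooth(contrast_map(fit, c(apple = 1, cup = -1)),
                    fwhm_mm, bold$spec$voxel_size_mm)
  }, bold_list, design_list, SIMPLIFY = FALSE)
  group_cluster_fwe(maps, tails = "both", ...)
}
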
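## File formats: events tables are tab-separated with header; volumes are
## NIfTI-1; fit results and cluster tables are CSV; configs round-trip
## through JSON.

EVENTS_COLUMNS <- c("run", "trial", "onset", "onset_model", "duration",
                    "trial_type", "prime", "amount", "delay", "side_of_later")

#' Write a trial schedule as a tab-separated events table
#'
#' @param schedule A `td_schedule` (with or without a `choice` column).
#' @param path Output path.
#' @export
write_events <- function(schedule, path) {
  cols <- intersect(c(EVENTS_COLUMNS, "choice"), names(schedule))
  utils::write.table(as.data.frame(schedule)[cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an events table written by [write_events()]
#'
#' Validates the delimiter and column schema; errors name the offending
#' column.
#'
#' @param path Input path.
#' @return A `td_schedule` data frame.
#' @export
read_events <- function(path) {
  header <- readLines(path, n = 1)
  if (!grepl("\t", header))
    stop("events file is not tab-separated: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(EVENTS_COLUMNS, names(df))
  if (length(missing))
    stop("events file lacks column(s): ", paste(missing, collapse = ", "))
  num <- c("run", "trial", "onset", "onset_model", "duration", "amount", "delay")
  for (cn in num) if (!is.numeric(df[[cn]]))
    stop("events column '", cn, "' is not numeric")
  bad <- !df$trial_type %in% c("TD", "PC")
  if (any(bad)) stop("invalid trial_type at row(s): ",
                     paste(utils::head(which(bad)), collapse = ", "))
  class(df) <- c("td_schedule", "data.frame")
  df
}

#' Write a 3-D or 4-D array as NIfTI-1
#'
#' The affine is diagonal with the voxel size; for a `bold_series` the TR
#' is stored in the pixdim time slot.
#'
#' @param x A `bold_series`, `td_accuracy_map`, or numeric array.
#' @param path Output `.nii` path.
#' @param voxel_size_mm Isotropic voxel size (taken from the object when
#'   available).
#' @export
write_volume <- function(x, path, voxel_size_mm = NULL) {
  if (inherits(x, "bold_series")) {
    arr <- x$data; vs <- x$spec$voxel_size_mm
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(vs, vs, vs, x$spec$tr_ms / 1000)
  } else {
    arr <- if (inherits(x, "td_accuracy_map")) x$accuracy else x
    vs <- if (!is.null(voxel_size_mm)) voxel_size_mm else
      if (inherits(x, "td_accuracy_map")) x$voxel_size_mm else 1
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rep(vs, 3)
  }
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path Input path.
#' @return Numeric array with attribute `pixdim`.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim(img))
  attr(out, "pixdim") <- RNifti::pixdim(img)
  out
}

#' Per-subject fit results table
#'
#' One row per subject with the parameter estimates, standard errors,
#' log-likelihoods, information criteria and likelihood-ratio comparison —
#' the layout of a subject-level model-comparison table.
#'
#' @param fits_base,fits_prime Lists of `td_fit` objects.
#' @return Data frame.
#' @export
fit_results_table <- function(fits_base, fits_prime) {
  stopifnot(length(fits_base) == length(fits_prime))
  rows <- lapply(seq_along(fits_base), function(i) {
    b <- fits_base[[i]]; p <- fits_prime[[i]]
    cmp <- compare_models(b, p)
    data.frame(subject = i,
               k_base = b$params$k, se_k_base = b$std_errors[["k"]],
               omega_base = b$params$omega, se_omega_base = b$std_errors[["omega"]],
               k = p$params$k, se_k = p$std_errors[["k"]],
               a = p$params$a, se_a = p$std_errors[["a"]],
               omega = p$params$omega, se_omega = p$std_errors[["omega"]],
               loglik_base = b$log_lik, loglik_prime = p$log_lik,
               lr = cmp$lr_statistic, p_lr = cmp$p_value,
               aic_base = b$aic, aic_prime = p$aic,
               bic_base = b$bic, bic_prime = p$bic,
               preferred = cmp$preferred)
  })
  do.call(rbind, rows)
}

#' Serialize / restore a pipeline configuration
#'
#' Round-trips the design, population and BOLD specifications (plus any
#' scalar options) through JSON losslessly.
#'
#' @param config Named list of specification objects / scalars.
#' @param path JSON path.
#' @export
write_config <- function(config, path) {
  ser <- lapply(config, function(x) {
    if (inherits(x, c("design_config", "population_spec", "bold_spec"))) {
      out <- unclass(x)
      out$.class <- class(x)[1]
      if (!is.null(out$regions)) {
        out$regions <- lapply(out$regions, function(r)
          list(voxels = unname(apply(r$voxels, 1, identity, simplify = FALSE)),
               effect = r$effect, size = r$size))
      }
      out
    } else x
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(x) {
    if (is.list(x) && !is.null(x$.class)) {
      cls <- x$.class
      x$.class <- NULL
      if (!is.null(x$regions) && length(x$regions)) {
        x$regions <- lapply(x$regions, function(r) {
          v <- if (is.list(r$voxels)) do.call(rbind, r$voxels) else
            as.matrix(r$voxels)
          list(voxels = v, effect = r$effect, size = r$size)
        })
      }
      args <- x
      switch(cls,
             design_config = do.call(design_config, args[names(formals(design_config))[
               names(formals(design_config)) %in% names(args)]]),
             population_spec = do.call(population_spec, args),
             bold_spec = do.call(bold_spec, args))
    } else x
  })
}

#' Derive stage-specific child seeds from a master seed
#'
#' Fixed arithmetic derivation so that pipeline stages are independently
#' re-runnable under one master seed; results stay below 2^31.
#'
#' @param master Integer master seed.
#' @param stage Stage name.
#' @param index Optional per-subject/per-replicate index.
#' @export
child_seed <- function(master, stage, index = 0L) {
  offs <- c(design = 101L, choices = 211L, visibility = 307L, bold = 401L,
            fit = 503L, glm = 601L, mvpa = 701L, report = 809L)
  if (!stage %in% names(offs)) stop("unknown stage: ", stage)
  # double arithmetic (exact below 2^53), reduced into 32-bit integer range
  as.integer((as.numeric(master) * 1009 + offs[[stage]] * 10007 +
                as.numeric(index)) %% 2147483647)
}
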
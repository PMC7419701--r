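# Block-design task-fMRI comparator: boxcar regressor convolved with a
# gamma-variate hemodynamic kernel, voxelwise least squares, 10 mm smoothing
# and brain masking of the resulting activation maps. No clustering and no
# thresholding are applied.

# hemodynamic response kernel sampled at the frame grid, integral 1
hrf_kernel <- function(tr, shape = 6, scale = 1, span_s = 30) {
  t_s <- seq(0, span_s, by = tr)
  k <- dgamma(t_s, shape = shape, scale = scale)
  k / sum(k)
}

# boxcar (0/1 task indicator) convolved with the hemodynamic kernel
task_regressor <- function(design, tr) {
  stopifnot(inherits(design, "glm_design"))
  box <- numeric(design$n_frames)
  for (on in design$block_onsets)
    box[on:(on + design$block_duration_frames - 1L)] <- 1
  k <- hrf_kernel(tr, design$hrf_shape, design$hrf_scale)
  out <- convolve(box, rev(k), type = "open")[seq_len(design$n_frames)]
  attr(out, "boxcar") <- box
  out
}

#' Build the GLM design matrix for a block task run
#'
#' Columns: intercept and the task regressor (block boxcar convolved with a
#' gamma-variate hemodynamic kernel whose integral is normalized to 1).
#' With no blocks the matrix is intercept-only.
#'
#' @param design A [glm_design()].
#' @param protocol The run's [acquisition_protocol()] (supplies TR and run
#'   length).
#' @return Numeric matrix (frames x columns) with columns `intercept` and,
#'   when blocks exist, `task`; the unconvolved boxcar is attached as
#'   attribute `boxcar`.
#' @export
build_design_matrix <- function(design, protocol) {
  stopifnot(inherits(design, "glm_design"), inherits(protocol, "acq_protocol"))
  if (design$n_frames != protocol$n_frames_per_run)
    stopf("design error: design covers %d frames, protocol acquires %d",
          design$n_frames, protocol$n_frames_per_run)
  if (!length(design$block_onsets)) {
    X <- matrix(1, design$n_frames, 1, dimnames = list(NULL, "intercept"))
    return(X)
  }
  reg <- task_regressor(design, protocol$tr)
  X <- cbind(intercept = 1, task = as.numeric(reg))
  attr(X, "boxcar") <- attr(reg, "boxcar")
  X
}

#' Fit the voxelwise general linear model
#'
#' Ordinary least squares per voxel over the kept frames; the activation map
#' carries the task-column coefficient (beta) and its t statistic
#' (beta / SE, residual dof = kept frames - columns).
#'
#' @param run A (typically preprocessed) `bold_run` containing the task run.
#' @param X Design matrix from [build_design_matrix()].
#' @param censor Optional `censor_mask`; censored frames are excluded from
#'   the fit.
#' @return Object of class `activation_map`: `beta`, `tstat` (3D volumes,
#'   zero outside the brain mask), `design_used`, `smoothing_fwhm` (0 until
#'   [postprocess_activation()]), `dof`.
#' @export
fit_glm <- function(run, X, censor = NULL) {
  stopifnot(inherits(run, "bold_run"))
  M <- run_as_matrix(run$data)
  keep <- if (is.null(censor)) rep(TRUE, nrow(M)) else censor$keep
  M <- M[keep, , drop = FALSE]
  Xk <- X[keep, , drop = FALSE]
  if (nrow(Xk) <= ncol(Xk) + 2)
    stopf("kept frames (%d) must exceed design columns + 2 (%d)",
          nrow(Xk), ncol(Xk) + 2)
  qx <- qr(Xk)
  if (qx$rank < ncol(Xk)) stopf("singular design matrix")
  task_col <- if ("task" %in% colnames(Xk)) which(colnames(Xk) == "task") else ncol(Xk)
  grid <- dim(run$data)[1:3]
  brain <- as.vector(run$brain_mask)
  B <- qr.coef(qx, M[, brain, drop = FALSE])
  res <- M[, brain, drop = FALSE] - Xk %*% B
  dof <- nrow(Xk) - ncol(Xk)
  sigma2 <- colSums(res^2) / dof
  xtxinv <- chol2inv(qr.R(qx))
  se <- sqrt(sigma2 * xtxinv[task_col, task_col])
  beta <- numeric(prod(grid))
  tstat <- numeric(prod(grid))
  beta[brain] <- B[task_col, ]
  tv <- B[task_col, ] / se
  tv[se == 0] <- 0
  tstat[brain] <- tv
  structure(list(beta = array(beta, grid), tstat = array(tstat, grid),
                 design_used = X, smoothing_fwhm = 0, dof = dof,
                 brain_mask = run$brain_mask,
                 voxel_size_mm = run$protocol$voxel_size_mm),
            class = "activation_map")
}

#' Post-process an activation map
#'
#' Gaussian-smooths the beta and t volumes (default 10 mm FWHM) and masks
#' out extra-cranial voxels. Neither cluster-level correction nor
#' thresholding is applied.
#'
#' @param map An `activation_map`.
#' @param fwhm_mm Smoothing FWHM in mm.
#' @param mask Logical brain mask (defaults to the map's own).
#' @return The smoothed, masked `activation_map`.
#' @export
postprocess_activation <- function(map, fwhm_mm = 10, mask = NULL) {
  stopifnot(inherits(map, "activation_map"))
  mask <- mask %||% map$brain_mask
  if (is.null(mask)) stopf("a brain mask is required")
  for (fld in c("beta", "tstat")) {
    v <- spatial_smooth(map[[fld]], fwhm_mm, map$voxel_size_mm)
    v[!mask] <- 0
    map[[fld]] <- v
  }
  map$smoothing_fwhm <- fwhm_mm
  map$brain_mask <- mask
  map
}

#' @export
print.activation_map <- function(x, ...) {
  cat(sprintf("Activation map: %s grid, dof %d, smoothing %g mm, max |t| = %.2f\n",
              paste(dim(x$beta), collapse = "x"), x$dof, x$smoothing_fwhm,
              max(abs(x$tstat))))
  invisible(x)
}
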
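# The fMRI denoising chain: voxelwise detrending, zero-phase low-pass
# filtering (<0.1 Hz), spatial Gaussian smoothing, nuisance/global-signal
# regression, and RMS frame censoring. The same code path serves rest and
# task runs.

#' Remove per-voxel linear trends
#'
#' Least-squares removal of an intercept and linear slope from every voxel
#' time series.
#'
#' @param run A `bold_run`.
#' @return The detrended `bold_run`.
#' @export
detrend_run <- function(run) {
  stopifnot(inherits(run, "bold_run"))
  nt <- dim(run$data)[4]
  if (nt < 3) stopf("insufficient data: detrending needs >= 3 frames, got %d", nt)
  M <- run_as_matrix(run$data)
  X <- cbind(1, seq_len(nt) - (nt + 1) / 2)
  M <- M - X %*% solve(crossprod(X), crossprod(X, M))
  run$data <- matrix_as_run(M, dim(run$data)[1:3])
  run
}

#' Zero-phase temporal low-pass filter
#'
#' Second-order Butterworth filter applied forward and backward (zero phase)
#' to every voxel series, retaining frequencies below `cutoff_hz`. The
#' squared-magnitude response of the forward-backward pass keeps >= 94% of
#' the amplitude at half the cutoff and <= 6% at twice the cutoff.
#'
#' @param run A `bold_run`.
#' @param cutoff_hz Passband edge in Hz; must be below Nyquist `1/(2 tr)`.
#' @return The filtered `bold_run`.
#' @export
lowpass_filter <- function(run, cutoff_hz = 0.1) {
  stopifnot(inherits(run, "bold_run"))
  nyq <- 1 / (2 * run$protocol$tr)
  if (cutoff_hz >= nyq)
    stopf("cutoff %.3f Hz is not below the Nyquist frequency %.3f Hz",
          cutoff_hz, nyq)
  M <- zero_phase_lowpass(run_as_matrix(run$data), cutoff_hz, run$protocol$tr)
  run$data <- matrix_as_run(M, dim(run$data)[1:3])
  run
}

# matrix version (frames x series); shared with the latent-signal generator
zero_phase_lowpass <- function(mat, cutoff_hz, tr) {
  nyq <- 1 / (2 * tr)
  if (cutoff_hz >= nyq) stopf("cutoff must be below Nyquist")
  ba <- signal::butter(2, cutoff_hz / nyq, type = "low")
  b <- as.numeric(ba$b)
  a <- as.numeric(ba$a)
  .filtfilt_mat_cpp(b, a, mat, filter_zi(b, a))
}

# steady-state initial filter conditions (scaled by the first padded sample)
filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, rep(0, n - length(a)))
  b <- c(b, rep(0, n - length(b)))
  m <- n - 1
  comp <- matrix(0, m, m)
  comp[1, ] <- -a[-1] / a[1]
  if (m > 1) comp[cbind(2:m, 1:(m - 1))] <- 1
  B <- b[-1] - a[-1] * b[1]
  solve(diag(m) - t(comp), B)
}

#' Spatial Gaussian smoothing
#'
#' Separable Gaussian blur with `sigma = fwhm / (2 sqrt(2 ln 2))` per axis in
#' mm, converted to voxels by the voxel size. Boundaries are handled by
#' half-sample symmetric reflection, which conserves total intensity.
#'
#' @param volume A 3D or 4D array, or a `bold_run` (every frame is smoothed).
#' @param fwhm_mm Full width at half maximum in mm (>= 0; 0 is the identity).
#' @param voxel_size_mm Voxel edge length in mm (taken from the protocol when
#'   a `bold_run` is given).
#' @return The smoothed array or `bold_run`.
#' @export
spatial_smooth <- function(volume, fwhm_mm, voxel_size_mm = 3) {
  if (fwhm_mm < 0) stopf("fwhm_mm must be >= 0")
  if (inherits(volume, "bold_run")) {
    volume$data <- spatial_smooth(volume$data, fwhm_mm,
                                  volume$protocol$voxel_size_mm)
    return(volume)
  }
  d <- dim(volume)
  if (is.null(d) || !(length(d) %in% c(3, 4)))
    stopf("volume must be a 3D or 4D array")
  k <- gaussian_kernel(fwhm_to_sigma_vox(fwhm_mm, voxel_size_mm))
  if (is.null(k)) return(volume)
  nvol <- if (length(d) == 4) d[4] else 1L
  out <- .sepconv3d_cpp(as.numeric(volume), d[1], d[2], d[3], nvol,
                        list(k, k, k))
  array(out, dim = d)
}

#' Assemble nuisance regressors for a run
#'
#' Columns: white-matter mean, CSF mean, whole-brain ("global") mean — each
#' extracted from the run as given (normally after detrending, filtering and
#' smoothing) — plus, when the run carries injected motion-spike frames, the
#' spike indicator and its temporal derivative as stand-ins for head-motion
#' realignment parameters.
#'
#' @param run A `bold_run`.
#' @param global_signal Include the whole-brain mean regressor?
#' @param lowpass_hz If non-NULL, the spike indicator columns are passed
#'   through the same zero-phase low-pass as the data so that the regression
#'   stays matched to the filtered series.
#' @return Object of class `nuisance_set`: `X` (frames x columns), `names`.
#' @export
build_nuisance <- function(run, global_signal = TRUE, lowpass_hz = NULL) {
  stopifnot(inherits(run, "bold_run"))
  M <- run_as_matrix(run$data)
  cols <- list()
  if (!is.null(run$wm_mask) && any(run$wm_mask))
    cols$wm <- rowMeans(M[, as.vector(run$wm_mask), drop = FALSE])
  if (!is.null(run$csf_mask) && any(run$csf_mask))
    cols$csf <- rowMeans(M[, as.vector(run$csf_mask), drop = FALSE])
  if (global_signal)
    cols$global <- rowMeans(M[, as.vector(run$brain_mask), drop = FALSE])
  if (length(run$motion_spike_frames)) {
    ind <- numeric(nrow(M))
    ind[run$motion_spike_frames] <- 1
    if (!is.null(lowpass_hz))
      ind <- as.vector(zero_phase_lowpass(matrix(ind, ncol = 1), lowpass_hz,
                                          run$protocol$tr))
    cols$spike <- ind
    cols$spike_deriv <- c(0, diff(ind))
  }
  if (!length(cols)) stopf("no nuisance columns could be built")
  structure(list(X = do.call(cbind, cols), names = names(cols)),
            class = "nuisance_set")
}

#' Regress nuisance waveforms out of every voxel
#'
#' Per-voxel least squares on the nuisance matrix (an intercept is added
#' internally); voxel series are replaced by their residuals, which are
#' orthogonal to every regressor.
#'
#' @param run A `bold_run`.
#' @param nuisance A `nuisance_set` (or plain matrix) with one row per frame.
#' @return The residual `bold_run`.
#' @export
regress_nuisance <- function(run, nuisance) {
  stopifnot(inherits(run, "bold_run"))
  X <- if (inherits(nuisance, "nuisance_set")) nuisance$X else as.matrix(nuisance)
  cn <- if (inherits(nuisance, "nuisance_set")) nuisance$names else colnames(X)
  nt <- dim(run$data)[4]
  if (nrow(X) != nt)
    stopf("nuisance matrix has %d rows but the run has %d frames", nrow(X), nt)
  Xi <- cbind(intercept = 1, X)
  qx <- qr(Xi)
  if (qx$rank < ncol(Xi)) {
    bad <- setdiff(seq_len(ncol(Xi)), qx$pivot[seq_len(qx$rank)])
    lab <- c("intercept", cn %||% paste0("V", seq_len(ncol(X))))
    stopf("nuisance design is rank deficient; collinear column(s): %s",
          paste(lab[bad], collapse = ", "))
  }
  M <- run_as_matrix(run$data)
  M <- M - Xi %*% qr.coef(qx, M)
  run$data <- matrix_as_run(M, dim(run$data)[1:3])
  run
}

#' Frame censoring by whole-brain RMS frame-to-frame change
#'
#' Computes, for every frame after the first, the root-mean-square (over
#' brain voxels) intensity change relative to the previous frame, expressed
#' as a percentage of the whole-brain mean intensity. Frames whose change
#' exceeds `threshold_percent` are excluded from all downstream correlation
#' computations; frame 1 is always kept. An isolated intensity spike flags
#' both transitions around it — the spike frame and its successor.
#'
#' @param run A `bold_run`.
#' @param threshold_percent Censoring threshold as percent of the whole-brain
#'   mean (default 0.5).
#' @return Object of class `censor_mask`: `keep` (logical per frame),
#'   `threshold_percent`, `rms_trace` (percent units).
#' @export
censor_frames <- function(run, threshold_percent = 0.5) {
  stopifnot(inherits(run, "bold_run"))
  if (!any(run$brain_mask)) stopf("brain mask is empty")
  M <- run_as_matrix(run$data)[, as.vector(run$brain_mask), drop = FALSE]
  gmean <- mean(M)
  d <- diff(M)
  rms <- c(0, sqrt(rowMeans(d^2))) / gmean * 100
  structure(list(keep = rms <= threshold_percent,
                 threshold_percent = threshold_percent,
                 rms_trace = rms),
            class = "censor_mask")
}

#' Default preprocessing configuration
#'
#' @param detrend Remove per-voxel linear trends?
#' @param lowpass_hz Low-pass cutoff in Hz (NULL disables filtering).
#' @param smooth_fwhm_mm Spatial smoothing FWHM in mm (0 disables).
#' @param nuisance Regress nuisance waveforms?
#' @param global_signal Include the global-signal regressor?
#' @param censor_threshold_percent RMS censoring threshold (percent).
#' @return A named list of stage parameters.
#' @export
preprocess_config <- function(detrend = TRUE, lowpass_hz = 0.1,
                              smooth_fwhm_mm = 6, nuisance = TRUE,
                              global_signal = TRUE,
                              censor_threshold_percent = 0.5) {
  list(detrend = detrend, lowpass_hz = lowpass_hz,
       smooth_fwhm_mm = smooth_fwhm_mm, nuisance = nuisance,
       global_signal = global_signal,
       censor_threshold_percent = censor_threshold_percent)
}

#' Run the full denoising chain on one run
#'
#' Applies, in order: detrending, zero-phase low-pass filtering, spatial
#' smoothing, and nuisance regression — identically for rest and task runs.
#' The censor mask is evaluated on the unprocessed data (motion artifacts are
#' assessed before denoising can smear or absorb them) and returned alongside
#' the processed run; downstream computations drop the censored frames.
#'
#' @param run A `bold_run`.
#' @param config A [preprocess_config()] list.
#' @return A list with elements `run` (processed `bold_run`), `censor`
#'   (`censor_mask`) and `stages` (character vector of applied stages).
#' @export
preprocess_run <- function(run, config = preprocess_config()) {
  stopifnot(inherits(run, "bold_run"))
  censor <- censor_frames(run, config$censor_threshold_percent %||% 0.5)
  stages <- character(0)
  if (isTRUE(config$detrend)) {
    run <- detrend_run(run)
    stages <- c(stages, "detrend")
  }
  if (!is.null(config$lowpass_hz)) {
    run <- lowpass_filter(run, config$lowpass_hz)
    stages <- c(stages, sprintf("lowpass<%g Hz", config$lowpass_hz))
  }
  if ((config$smooth_fwhm_mm %||% 0) > 0) {
    run <- spatial_smooth(run, config$smooth_fwhm_mm)
    stages <- c(stages, sprintf("smooth %g mm (reflective boundary)",
                                config$smooth_fwhm_mm))
  }
  if (isTRUE(config$nuisance)) {
    nui <- build_nuisance(run, global_signal = isTRUE(config$global_signal),
                          lowpass_hz = config$lowpass_hz)
    run <- regress_nuisance(run, nui)
    stages <- c(stages, paste0("nuisance[", paste(nui$names, collapse = ","), "]"))
  }
  stages <- c(stages, sprintf("censor>%g%%", censor$threshold_percent))
  list(run = run, censor = censor, stages = stages)
}

#' Pool preprocessed runs and keep censored-out frames excluded
#'
#' Concatenates the kept frames of several preprocessed runs of one subject
#' into a single frames-by-voxels matrix (the all-run "pooled" series).
#'
#' @param pp_list List of results from [preprocess_run()].
#' @return List with `mat` (kept frames x voxels), `brain_mask`, `grid_shape`,
#'   `frames_per_run` (kept frame counts).
#' @export
pool_runs <- function(pp_list) {
  stopifnot(length(pp_list) >= 1)
  mats <- lapply(pp_list, function(pp)
    run_as_matrix(pp$run$data)[pp$censor$keep, , drop = FALSE])
  list(mat = do.call(rbind, mats),
       brain_mask = pp_list[[1]]$run$brain_mask,
       grid_shape = dim(pp_list[[1]]$run$data)[1:3],
       frames_per_run = vapply(mats, nrow, 0L))
}

#' Select a contiguous frame subset from a pooled series
#'
#' Takes the first `n_frames` kept frames, used to match a shorter
#' acquisition (e.g. a 100-frame subset of a 320-frame rest series).
#'
#' @param pooled Result of [pool_runs()].
#' @param n_frames Number of frames to retain.
#' @return The pooled object restricted to the first `n_frames` frames.
#' @export
subset_frames <- function(pooled, n_frames) {
  if (n_frames > nrow(pooled$mat))
    stopf("requested %d frames but only %d kept frames are available",
          n_frames, nrow(pooled$mat))
  pooled$mat <- pooled$mat[seq_len(n_frames), , drop = FALSE]
  pooled$frames_per_run <- NULL
  pooled
}
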
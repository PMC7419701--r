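# Phantom BOLD simulation: rest runs, task runs and meta-analytic Z-maps with
# known network topography, so every downstream stage can be validated against
# planted structure.

#' Simulate a resting-state phantom run
#'
#' Each network carries one latent low-frequency time series (white Gaussian
#' noise low-pass filtered below 0.1 Hz, unit variance). A parcel voxel's
#' series is its network latent plus white noise (variance set by `snr` =
#' signal variance / noise variance) plus a voxel-specific linear drift, on
#' top of a constant whole-brain baseline intensity. White-matter and CSF
#' compartments carry their own latents; other in-brain background voxels are
#' noise only. Frames listed in `spike_frames` receive a whole-volume
#' intensity offset large enough to exceed the default frame-censoring
#' threshold (motion artifact proxy; geometric displacement is not modeled).
#'
#' @param roi_set A phantom atlas from [make_phantom_atlas()].
#' @param protocol An [acquisition_protocol()]; its grid must match the atlas.
#' @param snr Signal-to-noise variance ratio, >= 0. `Inf` gives noiseless
#'   series; `0` gives pure noise (no network signal).
#' @param drift_amplitude Scale of per-voxel linear drift (signal-sd units
#'   over the full run; each voxel's slope is uniform on +/- this value).
#' @param spike_frames Frames (1-based) receiving the artifact offset.
#' @param seed RNG seed.
#' @param baseline Whole-brain baseline intensity.
#' @param spike_magnitude Intensity offset for spike frames; default 5x the
#'   0.5 percent censoring threshold relative to `baseline`.
#' @param network_signal Set `FALSE` to suppress the latent network signals
#'   entirely (deterministic runs for exact-recovery checks).
#' @return An object of class `bold_run`: `data` (4D array x,y,z,frame),
#'   `protocol`, `brain_mask`, `motion_spike_frames`, plus the atlas nuisance
#'   compartments. The network latents are attached as attribute `latents`
#'   (frames x networks) for validation.
#' @export
simulate_rest_run <- function(roi_set, protocol, snr = 5, drift_amplitude = 1,
                              spike_frames = integer(0), seed = 1,
                              baseline = 1000, spike_magnitude = NULL,
                              network_signal = TRUE) {
  stopifnot(inherits(roi_set, "roi_set"), inherits(protocol, "acq_protocol"))
  if (!identical(as.integer(protocol$grid_shape), roi_set$grid_shape))
    stopf("protocol grid does not match the atlas grid")
  if (!is.numeric(snr) || length(snr) != 1 || snr < 0) stopf("snr must be >= 0")
  nt <- protocol$n_frames_per_run
  spike_frames <- as.integer(spike_frames)
  if (length(spike_frames) && (any(spike_frames < 1) || any(spike_frames > nt)))
    stopf("spike_frames outside the run range 1..%d", nt)
  spike_magnitude <- spike_magnitude %||% (5 * 0.005 * baseline)

  K <- max(roi_set$network_of_roi)
  grid <- roi_set$grid_shape
  nv <- prod(grid)
  brain <- as.vector(roi_set$brain_mask)
  labels <- as.vector(roi_set$label_volume)
  wm <- as.vector(roi_set$wm_mask)
  csf <- as.vector(roi_set$csf_mask)
  sig_amp <- if (snr == 0 || !network_signal) 0 else 1
  noise_sd <- if (is.infinite(snr)) 0 else if (snr == 0) 1 else 1 / sqrt(snr)

  out <- with_seed(seed, {
    latents <- sapply(seq_len(K + 2), function(i)
      latent_series(nt, protocol$tr))               # frames x (K networks + wm + csf)
    M <- matrix(0, nt, nv)
    for (k in seq_len(K)) {
      parcels <- which(roi_set$network_of_roi == k)
      vox <- which(brain & labels %in% parcels)
      if (length(vox)) M[, vox] <- sig_amp * latents[, k]
    }
    M[, which(wm)] <- sig_amp * latents[, K + 1]
    M[, which(csf)] <- sig_amp * latents[, K + 2]
    bidx <- which(brain)
    M[, bidx] <- M[, bidx] + noise_sd * matrix(rnorm(nt * length(bidx)), nt)
    slopes <- drift_amplitude * runif(length(bidx), -1, 1)
    tt <- seq(-0.5, 0.5, length.out = nt)
    M[, bidx] <- M[, bidx] + outer(tt, slopes)
    M[, bidx] <- M[, bidx] + baseline
    if (length(spike_frames))
      M[spike_frames, bidx] <- M[spike_frames, bidx] + spike_magnitude
    list(M = M, latents = latents[, seq_len(K), drop = FALSE])
  })

  run <- structure(list(data = matrix_as_run(out$M, grid),
                        protocol = protocol,
                        brain_mask = roi_set$brain_mask,
                        motion_spike_frames = spike_frames,
                        wm_mask = roi_set$wm_mask,
                        csf_mask = roi_set$csf_mask),
                   class = "bold_run")
  attr(run, "latents") <- out$latents
  run
}

# One latent: white Gaussian noise band-limited below `cutoff_hz` by an FFT
# brick wall, standardized. The band sits inside the pipeline's 0.1 Hz
# passband so the planted correlation structure survives the denoising
# filter essentially unchanged.
latent_series <- function(nt, tr, cutoff_hz = 0.08) {
  x <- rnorm(nt)
  freqs <- (seq_len(nt) - 1) / (nt * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)          # two-sided frequency axis
  if (any(freqs > cutoff_hz)) {
    X <- fft(x)
    X[freqs > cutoff_hz] <- 0
    x <- Re(fft(X, inverse = TRUE)) / nt
  }
  (x - mean(x)) / sd(x)
}

#' Simulate a block-design task phantom run
#'
#' Builds a rest-like run (identical RNG stream, so `amplitude = 0`
#' reproduces [simulate_rest_run()] exactly) and adds the hemodynamic task
#' regressor — the block boxcar convolved with a gamma-variate kernel —
#' scaled by `amplitude`, to every voxel of the responsive parcels.
#'
#' @inheritParams simulate_rest_run
#' @param design A [glm_design()]; must fit within the protocol's run length.
#' @param responsive_parcels Parcel ids receiving the task response.
#' @param amplitude Response amplitude(s) in signal-sd units; recycled across
#'   `responsive_parcels`.
#' @return A `bold_run`; the design is attached as attribute `design` and the
#'   regressor as attribute `task_regressor`.
#' @export
simulate_task_run <- function(roi_set, protocol, design,
                              responsive_parcels = roi_set$language_parcels,
                              amplitude = 1, snr = 5, drift_amplitude = 1,
                              spike_frames = integer(0), seed = 1, ...) {
  stopifnot(inherits(design, "glm_design"))
  if (design$n_frames != protocol$n_frames_per_run)
    stopf("design is for %d frames but the protocol acquires %d",
          design$n_frames, protocol$n_frames_per_run)
  responsive_parcels <- as.integer(responsive_parcels)
  known <- as.integer(names(roi_set$network_of_roi))
  if (!all(responsive_parcels %in% known))
    stopf("unknown parcel id(s): %s",
          paste(setdiff(responsive_parcels, known), collapse = ", "))
  run <- simulate_rest_run(roi_set, protocol, snr = snr,
                           drift_amplitude = drift_amplitude,
                           spike_frames = spike_frames, seed = seed, ...)
  reg <- task_regressor(design, protocol$tr)
  amp <- rep_len(amplitude, length(responsive_parcels))
  labels <- as.vector(roi_set$label_volume)
  M <- run_as_matrix(run$data)
  for (i in seq_along(responsive_parcels)) {
    vox <- which(labels == responsive_parcels[i])
    M[, vox] <- M[, vox] + amp[i] * reg
  }
  run$data <- matrix_as_run(M, roi_set$grid_shape)
  attr(run, "design") <- design
  attr(run, "task_regressor") <- reg
  run
}

#' Simulate a meta-analytic Z-score map
#'
#' Produces a Z-score volume with Gaussian blobs centered on the atlas'
#' Broca- and Wernicke-like parcels, an optional smaller left-hemisphere
#' distractor blob, and small Gaussian background noise — a phantom stand-in
#' for a meta-analytic language-association map.
#'
#' @param roi_set A phantom atlas.
#' @param peak_z Peak Z of the two language blobs (must exceed 3.7 for the
#'   downstream ROI construction to find two clusters).
#' @param blob_fwhm_mm FWHM of the language blobs in mm.
#' @param seed RNG seed for the background noise.
#' @param distractor `TRUE` for the default smaller distractor (peak 5,
#'   0.6x the language FWHM, left hemisphere), `FALSE`/`NULL` for none, or a
#'   list with `peak_z`, `fwhm_mm`, `center`.
#' @param noise_sd Background Z noise standard deviation.
#' @return Object of class `meta_map`: `zvolume`, `space_tag`,
#'   `voxel_size_mm`, `planted_centers` (2 x 3, Broca then Wernicke) and
#'   `distractor_center` (or NULL).
#' @export
simulate_meta_map <- function(roi_set, peak_z = 8, blob_fwhm_mm = 12,
                              seed = 1, distractor = TRUE, noise_sd = 0.2) {
  stopifnot(inherits(roi_set, "roi_set"))
  grid <- roi_set$grid_shape
  ctrs <- roi_set$centers[roi_set$language_parcels, , drop = FALSE]
  sigma <- fwhm_to_sigma_vox(blob_fwhm_mm, roi_set$voxel_size_mm)
  z <- with_seed(seed, array(rnorm(prod(grid), sd = noise_sd), grid))
  for (i in 1:2) z <- z + gaussian_blob(grid, ctrs[i, ], sigma, peak_z)

  dctr <- NULL
  if (isTRUE(distractor) || is.list(distractor)) {
    if (isTRUE(distractor)) {
      dctr <- round((ctrs[1, ] + ctrs[2, ]) / 2)
      shift <- round(0.35 * grid[3])
      dctr[3] <- if (dctr[3] + shift <= grid[3] - 1) dctr[3] + shift else dctr[3] - shift
      distractor <- list(peak_z = 5, fwhm_mm = 0.6 * blob_fwhm_mm, center = dctr)
    }
    dctr <- distractor$center
    z <- z + gaussian_blob(grid, dctr,
                           fwhm_to_sigma_vox(distractor$fwhm_mm,
                                             roi_set$voxel_size_mm),
                           distractor$peak_z)
  }
  structure(list(zvolume = z,
                 space_tag = sprintf("phantom-%s-%gmm",
                                     paste(grid, collapse = "x"),
                                     roi_set$voxel_size_mm),
                 voxel_size_mm = roi_set$voxel_size_mm,
                 planted_centers = ctrs,
                 distractor_center = dctr),
            class = "meta_map")
}

gaussian_blob <- function(grid, center, sigma_vox, peak) {
  x <- (seq_len(grid[1]) - center[1])^2
  y <- (seq_len(grid[2]) - center[2])^2
  z <- (seq_len(grid[3]) - center[3])^2
  peak * exp(-outer(outer(x, y, "+"), z, "+") / (2 * sigma_vox^2))
}
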
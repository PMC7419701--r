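#' Acquisition protocol for a phantom BOLD run
#'
#' Describes the timing and geometry of one functional acquisition: seconds
#' per frame (TR), frames per run, number of runs, isotropic voxel size and
#' the voxel grid. The package defaults mirror a clinical presurgical rest
#' protocol (TR 2.2 s, two 160-frame rest runs) on a desk-scale 24-cubed grid
#' of 3 mm voxels.
#'
#' @param tr Repetition time in seconds per frame; must be positive.
#' @param n_frames_per_run Frames in one run (>= 1).
#' @param n_runs Number of runs acquired with this protocol (>= 1).
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param grid_shape Integer vector of length 3, voxels per axis (each >= 8).
#' @return An object of class `acq_protocol`.
#' @examples
#' rest_protocol <- acquisition_protocol(tr = 2.2, n_frames_per_run = 160,
#'                                       n_runs = 2, grid_shape = c(24, 24, 24))
#' @export
acquisition_protocol <- function(tr = 2.2, n_frames_per_run = 160, n_runs = 2,
                                 voxel_size_mm = 3, grid_shape = c(24, 24, 24)) {
  if (!is.numeric(tr) || tr <= 0) stopf("tr must be > 0")
  if (n_frames_per_run < 1 || n_runs < 1) stopf("frame and run counts must be >= 1")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 8))
    stopf("grid_shape must have 3 axes, each >= 8 voxels")
  structure(list(tr = tr,
                 n_frames_per_run = as.integer(n_frames_per_run),
                 n_runs = as.integer(n_runs),
                 voxel_size_mm = voxel_size_mm,
                 grid_shape = grid_shape),
            class = "acq_protocol")
}

#' Block design for a task run
#'
#' A boxcar block design: task blocks of fixed duration at given onset frames,
#' to be convolved with a hemodynamic response kernel. The default is the
#' word-generation style design of five alternating task/rest blocks of 10
#' frames each within a 100-frame run.
#'
#' @param block_onsets 1-based first frames of each task block.
#' @param block_duration_frames Frames per task block.
#' @param n_frames Total frames of the run the design belongs to.
#' @param hrf_shape,hrf_scale Shape and scale (seconds) of the gamma-variate
#'   hemodynamic kernel; the default peaks near 5 s.
#' @return An object of class `glm_design`.
#' @examples
#' d <- glm_design()  # 5 task blocks of 10 frames in a 100-frame run
#' @export
glm_design <- function(block_onsets = c(11, 31, 51, 71, 91),
                       block_duration_frames = 10, n_frames = 100,
                       hrf_shape = 6, hrf_scale = 1) {
  block_onsets <- as.integer(block_onsets)
  dur <- as.integer(block_duration_frames)
  if (length(block_onsets) > 0) {
    if (any(block_onsets < 1) || any(block_onsets + dur - 1L > n_frames))
      stopf("task blocks must lie within the %d-frame run", n_frames)
    ends <- block_onsets + dur - 1L
    ord <- order(block_onsets)
    if (length(block_onsets) > 1 &&
        any(block_onsets[ord][-1] <= ends[ord][-length(ends)]))
      stopf("task blocks must not overlap")
  }
  structure(list(block_onsets = block_onsets,
                 block_duration_frames = dur,
                 n_frames = as.integer(n_frames),
                 hrf_shape = hrf_shape, hrf_scale = hrf_scale),
            class = "glm_design")
}
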
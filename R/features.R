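# Seed-correlation feature volumes: the classifier's input representation.
# One training example is the whole-brain Fisher-z correlation volume of a
# parcel-mean seed, labeled by the seed's network; at inference time the seed
# is a single voxel's series, yielding voxelwise network probabilities.

#' Split example indices into train and validation partitions
#'
#' Deterministic shuffled partition: `round(n * fractions[1])` examples go to
#' the training set and the remainder to validation (so 268,000 examples at
#' the default 0.7/0.3 split give 187,600 training and 80,400 validation).
#'
#' @param n Number of examples.
#' @param fractions Train/validation fractions, summing to 1.
#' @param seed RNG seed for the shuffle.
#' @return A factor of length `n` with levels `train`, `validation`.
#' @export
partition_indices <- function(n, fractions = c(0.7, 0.3), seed = 1) {
  if (length(fractions) != 2 || abs(sum(fractions) - 1) > 1e-8)
    stopf("fractions must be two numbers summing to 1")
  n_train <- round(n * fractions[1])
  part <- rep("validation", n)
  idx <- with_seed(seed, sample.int(n))
  part[idx[seq_len(n_train)]] <- "train"
  factor(part, levels = c("train", "validation"))
}

#' Mean time series of every parcel
#'
#' @param run A `bold_run`, or a pooled series from [pool_runs()].
#' @param roi_set The phantom atlas.
#' @param censor Optional `censor_mask`; censored frames are dropped
#'   (ignored for pooled input, which is already censored).
#' @return Matrix of kept frames x parcels; column r is the mean series over
#'   the in-mask voxels of parcel r.
#' @export
extract_roi_timeseries <- function(run, roi_set, censor = NULL) {
  if (inherits(run, "bold_run")) {
    M <- run_as_matrix(run$data)
    if (!is.null(censor)) M <- M[censor$keep, , drop = FALSE]
    brain <- as.vector(run$brain_mask)
  } else {
    M <- run$mat
    brain <- as.vector(run$brain_mask)
  }
  labels <- as.vector(roi_set$label_volume)
  ids <- sort(unique(labels[labels > 0]))
  out <- vapply(ids, function(r) {
    vox <- which(labels == r & brain)
    if (!length(vox))
      stopf("parcel %d has no voxels inside the brain mask", r)
    rowMeans(M[, vox, drop = FALSE])
  }, numeric(nrow(M)))
  colnames(out) <- as.character(ids)
  out
}

#' Whole-brain seed-correlation volume
#'
#' Pearson correlation of every voxel's series with a seed series over the
#' kept frames, Fisher z-transformed (r clamped to |r| <= 1 - 1e-7).
#'
#' @param run A `bold_run` or pooled series from [pool_runs()].
#' @param seed_series Numeric seed series, one value per kept frame.
#' @param censor Optional `censor_mask` applied to a `bold_run`.
#' @param downsample Integer block-averaging factor applied to the target
#'   grid before correlating (1 = full resolution).
#' @param seed_id Optional parcel id annotation.
#' @return Object of class `correlation_volume`: `values` (3D Fisher-z
#'   array), `seed_id`, `frames_used`.
#' @export
seed_correlation_volume <- function(run, seed_series, censor = NULL,
                                    downsample = 1L, seed_id = NA) {
  if (inherits(run, "bold_run")) {
    M <- run_as_matrix(run$data)
    if (!is.null(censor)) M <- M[censor$keep, , drop = FALSE]
    grid <- dim(run$data)[1:3]
  } else {
    M <- run$mat
    grid <- run$grid_shape
  }
  if (length(seed_series) != nrow(M))
    stopf("seed series length %d does not match the %d kept frames",
          length(seed_series), nrow(M))
  if (sd(seed_series) <= 0 || !is.finite(sd(seed_series)))
    stopf("degenerate seed: zero-variance series")
  ds <- downsample_grid(M, grid, downsample)
  z <- corr_with_seed(ds$mat, seed_series)
  structure(list(values = array(z, ds$grid),
                 seed_id = seed_id,
                 frames_used = nrow(M)),
            class = "correlation_volume")
}

# Fisher-z correlations of every column of mat with one seed series
corr_with_seed <- function(mat, seed_series) {
  Z <- standardize_cols(mat)
  s <- as.vector(standardize_cols(matrix(seed_series, ncol = 1)))
  r <- as.vector(crossprod(s, Z)) / (nrow(mat) - 1)
  r[attr(Z, "degenerate")] <- 0
  fisher_z(r)
}

# block-average the spatial grid of a frames x voxels matrix
downsample_grid <- function(mat, grid, factor) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(list(mat = mat, grid = as.integer(grid)))
  arr <- array(t(mat), dim = c(grid, 1L, nrow(mat)))
  pooled <- .avgpool3d_fwd_cpp(as.numeric(arr),
                               as.integer(c(grid, 1L, nrow(mat))), factor)
  pg <- dim(pooled)[1:3]
  list(mat = t(matrix(pooled, nrow = prod(pg))), grid = pg)
}

#' Build a labeled classifier example set from a cohort
#'
#' One example per (subject, seed parcel): the whole-brain Fisher-z
#' correlation volume of the parcel-mean seed, labeled with the parcel's
#' network, shuffled and partitioned into train/validation sets.
#'
#' @param cohort List of pooled subject series (each from [pool_runs()]).
#' @param roi_set The phantom atlas.
#' @param split_fractions Train/validation fractions.
#' @param seed RNG seed for shuffling/partitioning.
#' @param downsample Block-averaging factor for the correlation target grid.
#' @param min_frames Minimum kept frames for a valid correlation; subjects
#'   below it are excluded with a warning.
#' @return Object of class `example_set`: `volumes` (examples x voxels
#'   matrix of flattened correlation volumes), `labels` (network ids),
#'   `partition` (factor), `input_shape`, `subject` (index per example).
#' @export
build_training_examples <- function(cohort, roi_set,
                                    split_fractions = c(0.7, 0.3), seed = 1,
                                    downsample = 1L, min_frames = 30) {
  stopifnot(length(cohort) >= 1)
  vols <- list(); labs <- integer(0); subj <- integer(0)
  shape <- NULL
  for (s in seq_along(cohort)) {
    pooled <- cohort[[s]]
    if (nrow(pooled$mat) < min_frames) {
      warning(sprintf("subject %d excluded: only %d kept frames (< %d)",
                      s, nrow(pooled$mat), min_frames))
      next
    }
    ts <- extract_roi_timeseries(pooled, roi_set)
    ds <- downsample_grid(pooled$mat, pooled$grid_shape, downsample)
    shape <- ds$grid
    for (r in seq_len(ncol(ts))) {
      if (sd(ts[, r]) <= 0) {
        warning(sprintf("subject %d parcel %s skipped: degenerate seed",
                        s, colnames(ts)[r]))
        next
      }
      vols[[length(vols) + 1L]] <- corr_with_seed(ds$mat, ts[, r])
      labs <- c(labs, roi_set$network_of_roi[[colnames(ts)[r]]])
      subj <- c(subj, s)
    }
  }
  if (!length(vols)) stopf("no usable examples could be built")
  volumes <- do.call(rbind, vols)
  part <- partition_indices(nrow(volumes), split_fractions, seed)
  structure(list(volumes = volumes, labels = labs, partition = part,
                 input_shape = as.integer(shape), subject = subj,
                 n_classes = max(roi_set$network_of_roi)),
            class = "example_set")
}

#' @export
print.example_set <- function(x, ...) {
  cat(sprintf("Example set: %d correlation volumes (%s input), %d classes; %d train / %d validation\n",
              nrow(x$volumes), paste(x$input_shape, collapse = "x"),
              x$n_classes, sum(x$partition == "train"),
              sum(x$partition == "validation")))
  invisible(x)
}

#' Stream per-voxel inference examples
#'
#' Returns a chunked iterator over the in-mask voxels of a pooled subject
#' series, in raster order (x fastest, then y, then z). Each chunk holds the
#' whole-brain Fisher-z correlation volumes using each voxel's own series as
#' the seed. Zero-variance (degenerate) voxels are flagged so the classifier
#' can assign them uniform probabilities.
#'
#' @param pooled Pooled subject series from [pool_runs()] (optionally
#'   restricted with [subset_frames()]).
#' @param mask Optional logical volume restricting the seed voxels (default:
#'   the pooled brain mask).
#' @param chunk_size Voxels per chunk.
#' @param downsample Block-averaging factor for the correlation target grid.
#' @return A function; each call yields `list(z, voxels, degenerate)` or
#'   `NULL` when the stream is exhausted. The stream exposes the attributes
#'   `n_voxels` and `input_shape`.
#' @export
build_inference_examples <- function(pooled, mask = NULL, chunk_size = 512L,
                                     downsample = 1L) {
  mask <- mask %||% pooled$brain_mask
  voxels <- which(as.vector(mask))
  if (!length(voxels)) stopf("inference mask is empty")
  ds <- downsample_grid(pooled$mat, pooled$grid_shape, downsample)
  Zt <- standardize_cols(ds$mat)
  Zs <- standardize_cols(pooled$mat[, voxels, drop = FALSE])
  degen_seed <- attr(Zs, "degenerate")
  degen_tgt <- attr(Zt, "degenerate")
  nT <- nrow(pooled$mat)
  pos <- 0L
  stream <- function() {
    if (pos >= length(voxels)) return(NULL)
    idx <- (pos + 1L):min(pos + chunk_size, length(voxels))
    pos <<- idx[length(idx)]
    r <- crossprod(Zs[, idx, drop = FALSE], Zt) / (nT - 1)
    r[, degen_tgt] <- 0
    r[degen_seed[idx], ] <- 0
    list(z = fisher_z(r), voxels = voxels[idx],
         degenerate = degen_seed[idx])
  }
  attr(stream, "n_voxels") <- length(voxels)
  attr(stream, "input_shape") <- ds$grid
  attr(stream, "frames_used") <- nT
  stream
}
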
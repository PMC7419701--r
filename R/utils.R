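# Internal helpers shared across the pipeline.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# FWHM (mm) -> Gaussian sigma in voxel units.
fwhm_to_sigma_vox <- function(fwhm_mm, voxel_mm) {
  fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
}

# Normalized discrete Gaussian kernel for one axis; NULL if effectively a
# delta (sigma ~ 0).
gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox <= 1e-8) return(NULL)
  r <- max(1L, as.integer(ceiling(3.5 * sigma_vox)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Fisher z with clamping so |r| <= 1 - eps stays finite.
fisher_z <- function(r, eps = 1e-7) {
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

# Flatten a 4D (x,y,z,t) array to a frames x voxels matrix and back.
run_as_matrix <- function(data4d) {
  d <- dim(data4d)
  t(matrix(data4d, nrow = prod(d[1:3]), ncol = d[4]))
}

matrix_as_run <- function(mat, grid_shape) {
  array(t(mat), dim = c(grid_shape, nrow(mat)))
}

# Column-standardize (mean 0, unit sample sd); zero-variance columns -> NA
# marker returned in attr "degenerate".
standardize_cols <- function(mat) {
  mu <- colMeans(mat)
  xc <- sweep(mat, 2, mu)
  s <- sqrt(colSums(xc^2) / (nrow(mat) - 1))
  degen <- s <= 0 | !is.finite(s)
  s[degen] <- 1
  out <- sweep(xc, 2, s, "/")
  attr(out, "degenerate") <- degen
  out
}

# Voxel coordinates (rows) of TRUE entries of a 3D mask, in raster order
# (x fastest, then y, then z).
mask_coords <- function(mask) {
  which(mask, arr.ind = TRUE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
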
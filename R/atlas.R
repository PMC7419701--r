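#' Generate a phantom parcellation with planted resting-state networks
#'
#' Places `n_networks * rois_per_network` disjoint spherical parcels inside an
#' ellipsoidal brain mask on a candidate lattice, assigns each parcel to a
#' network, and designates network 1 as the language-analog network whose
#' first two parcels are a left-anterior ("Broca-like") and a left-posterior
#' ("Wernicke-like") parcel. Two additional background blobs serve as
#' white-matter and CSF compartments for nuisance regression. The x axis is
#' left-right with left = lower x index; the y axis is anterior-posterior
#' with anterior = lower y index.
#'
#' @param grid_shape Voxels per axis (length 3, each >= 8).
#' @param n_networks Number of networks K (>= 2).
#' @param rois_per_network Parcels per network (>= 2 for the language network).
#' @param seed RNG seed; the same seed reproduces the atlas bit for bit.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param parcel_radius Parcel sphere radius in voxels.
#' @return An object of class `roi_set` with fields `label_volume` (integer
#'   3D array, 0 = background), `network_of_roi` (parcel id -> network id),
#'   `centers` (parcel centroids, voxel coordinates), `brain_mask`, `wm_mask`,
#'   `csf_mask`, `language_network`, `language_parcels` (named ids of the
#'   Broca-/Wernicke-like parcels), `voxel_size_mm` and `grid_shape`.
#' @examples
#' atlas <- make_phantom_atlas(c(16, 16, 16), n_networks = 3,
#'                             rois_per_network = 2, seed = 1)
#' table(atlas$label_volume > 0)
#' @export
make_phantom_atlas <- function(grid_shape = c(24, 24, 24), n_networks = 6,
                               rois_per_network = 4, seed = 1,
                               voxel_size_mm = 3, parcel_radius = 1.5) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 8))
    stopf("grid_shape must have 3 axes, each >= 8 voxels")
  if (n_networks < 2) stopf("need at least 2 networks")
  if (rois_per_network < 2)
    stopf("need >= 2 parcels per network (the language network carries two)")
  n_parcels <- n_networks * rois_per_network

  ctr <- (grid_shape + 1) / 2
  radii <- pmax(3, round(0.42 * grid_shape))

  # quick packing bound: parcels cannot outnumber the brain volume
  sphere_n <- sum(as.vector(sphere_offsets(parcel_radius)$inside))
  brain_n <- ellipsoid_mask(grid_shape, ctr, radii)
  if ((n_parcels + 2) * sphere_n > sum(brain_n))
    stopf("capacity error: %d parcels of ~%d voxels exceed the %d-voxel brain",
          n_parcels, sphere_n, sum(brain_n))

  spacing <- max(4L, as.integer(ceiling(2 * parcel_radius + 1)))
  sites <- lattice_sites(grid_shape, ctr, radii, parcel_radius, spacing)
  if (nrow(sites) < n_parcels + 2)
    stopf("capacity error: grid admits %d parcel sites but %d are required (%d parcels + 2 nuisance compartments)",
          nrow(sites), n_parcels + 2, n_parcels)

  # language pair: most anterior / most posterior site in the left hemisphere
  left <- sites[sites[, 1] < ctr[1], , drop = FALSE]
  if (nrow(left) < 2)
    stopf("capacity error: fewer than 2 candidate sites in the left hemisphere")
  broca_c <- left[order(left[, 2], left[, 1])[1], ]
  left2 <- left[!(left[, 1] == broca_c[1] & left[, 2] == broca_c[2] &
                    left[, 3] == broca_c[3]), , drop = FALSE]
  wern_c <- left2[order(-left2[, 2], left2[, 1])[1], ]
  if (wern_c[2] <= broca_c[2])
    stopf("capacity error: cannot place an anterior/posterior language pair")

  used <- apply(sites, 1, function(s)
    all(s == broca_c) || all(s == wern_c))
  pool <- sites[!used, , drop = FALSE]
  centers <- with_seed(seed, {
    pick <- sample(nrow(pool), n_parcels - 2 + 2)
    pool[pick, , drop = FALSE]
  })
  parcel_centers <- rbind(broca_c, wern_c,
                          centers[seq_len(n_parcels - 2), , drop = FALSE])
  rownames(parcel_centers) <- NULL
  wm_c <- centers[n_parcels - 1, ]
  csf_c <- centers[n_parcels, ]

  label <- array(0L, dim = grid_shape)
  for (r in seq_len(n_parcels)) {
    idx <- sphere_voxels(parcel_centers[r, ], parcel_radius, grid_shape)
    if (any(label[idx] != 0L)) stopf("internal error: parcel overlap")
    label[idx] <- r
  }
  wm_mask <- array(FALSE, grid_shape)
  wm_mask[sphere_voxels(wm_c, parcel_radius, grid_shape)] <- TRUE
  csf_mask <- array(FALSE, grid_shape)
  csf_mask[sphere_voxels(csf_c, parcel_radius, grid_shape)] <- TRUE

  brain_mask <- array(brain_n, grid_shape)
  network_of_roi <- rep(seq_len(n_networks), each = rois_per_network)
  names(network_of_roi) <- as.character(seq_len(n_parcels))

  structure(list(label_volume = label,
                 network_of_roi = network_of_roi,
                 centers = parcel_centers,
                 brain_mask = brain_mask,
                 wm_mask = wm_mask, csf_mask = csf_mask,
                 language_network = 1L,
                 language_parcels = c(broca = 1L, wernicke = 2L),
                 voxel_size_mm = voxel_size_mm,
                 grid_shape = grid_shape),
            class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("Phantom parcellation: %d parcels in %d networks on a %s grid\n",
              length(x$network_of_roi), max(x$network_of_roi),
              paste(x$grid_shape, collapse = "x")))
  cat(sprintf("  language network %d, Broca-like parcel %d, Wernicke-like parcel %d\n",
              x$language_network, x$language_parcels["broca"],
              x$language_parcels["wernicke"]))
  cat(sprintf("  brain mask: %d voxels (%.0f%% of grid)\n",
              sum(x$brain_mask), 100 * mean(x$brain_mask)))
  invisible(x)
}

# logical vector over the full grid: inside the ellipsoid centred at ctr
ellipsoid_mask <- function(grid_shape, ctr, radii) {
  x <- (seq_len(grid_shape[1]) - ctr[1]) / radii[1]
  y <- (seq_len(grid_shape[2]) - ctr[2]) / radii[2]
  z <- (seq_len(grid_shape[3]) - ctr[3]) / radii[3]
  d2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  d2 <= 1
}

sphere_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  inside <- g$dx^2 + g$dy^2 + g$dz^2 <= radius^2
  list(offsets = as.matrix(g), inside = inside)
}

# linear indices of the sphere around a center, clipped to the grid
sphere_voxels <- function(center, radius, grid_shape) {
  so <- sphere_offsets(radius)
  pts <- sweep(so$offsets[so$inside, , drop = FALSE], 2, center, "+")
  ok <- pts[, 1] >= 1 & pts[, 1] <= grid_shape[1] &
    pts[, 2] >= 1 & pts[, 2] <= grid_shape[2] &
    pts[, 3] >= 1 & pts[, 3] <= grid_shape[3]
  pts <- pts[ok, , drop = FALSE]
  pts[, 1] + grid_shape[1] * (pts[, 2] - 1) +
    prod(grid_shape[1:2]) * (pts[, 3] - 1)
}

# candidate parcel centers: lattice through the grid center, inside the brain
# ellipsoid shrunk by the parcel radius
lattice_sites <- function(grid_shape, ctr, radii, parcel_radius, spacing) {
  ax <- function(n, c0) {
    lo <- -floor((c0 - 1) / spacing)
    hi <- floor((n - c0) / spacing)
    c0 + spacing * (lo:hi)
  }
  g <- as.matrix(expand.grid(x = ax(grid_shape[1], floor(ctr[1])),
                             y = ax(grid_shape[2], floor(ctr[2])),
                             z = ax(grid_shape[3], floor(ctr[3]))))
  d2 <- ((g[, 1] - ctr[1]) / pmax(radii[1] - parcel_radius, 1e-6))^2 +
    ((g[, 2] - ctr[2]) / pmax(radii[2] - parcel_radius, 1e-6))^2 +
    ((g[, 3] - ctr[3]) / pmax(radii[3] - parcel_radius, 1e-6))^2
  g[d2 <= 1, , drop = FALSE]
}
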
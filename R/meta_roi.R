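# Ground-truth language ROI construction from a meta-analytic Z-map:
# smooth (1 mm) -> tanh probability transform / threshold Z > 3.7 -> keep the
# two largest left-hemisphere clusters -> smooth each indicator (3 mm) and
# re-binarize -> resolve overlaps by nearest center of mass. The anterior
# cluster is named Broca-like, the posterior Wernicke-like.

#' Label connected components of a boolean volume
#'
#' @param mask Logical 3D array.
#' @param connectivity Voxel neighborhood: 26 (faces, edges, corners) or 6
#'   (faces only).
#' @return List with `labels` (integer volume, 0 = background) and `sizes`
#'   (voxel count per component, ordered by label).
#' @export
connected_components <- function(mask, connectivity = 26) {
  if (!connectivity %in% c(6, 26)) stopf("connectivity must be 6 or 26")
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  labels <- .label_components_cpp(as.vector(mask), as.integer(dim(mask)),
                                  as.integer(connectivity))
  n <- max(labels)
  sizes <- if (n > 0) tabulate(labels[labels > 0], nbins = n) else integer(0)
  list(labels = labels, sizes = sizes)
}

#' Center of mass of a mask or weighted volume
#'
#' Intensity-weighted mean voxel position, mapped to mm by the voxel size
#' (mm coordinate = voxel index * voxel size).
#'
#' @param volume Logical mask or non-negative weight volume (3D).
#' @param voxel_size_mm Isotropic voxel size.
#' @return Numeric length-3 mm coordinates.
#' @export
center_of_mass <- function(volume, voxel_size_mm = 1) {
  w <- as.numeric(volume)
  if (sum(w) <= 0) stopf("center of mass of empty support")
  idx <- which(w > 0)
  coords <- arrayInd(idx, dim(volume))
  as.vector(colSums(coords * w[idx]) / sum(w[idx])) * voxel_size_mm
}

#' Construct disjoint Broca- and Wernicke-like ROIs from a Z-map
#'
#' Executes the five construction steps in order: (1) Gaussian smooth at
#' `smooth1_fwhm` mm; (2) transform positive Z-scores to probabilities with
#' the hyperbolic tangent and threshold at Z > `z_threshold` (thresholding is
#' performed in Z units; tanh is order-preserving, so cluster membership is
#' identical either way and the tanh map is kept as annotation); (3) restrict
#' to the left hemisphere (x below the grid midline) and retain the two
#' largest connected clusters; (4) Gaussian smooth each cluster's indicator
#' at `smooth2_fwhm` mm and re-binarize at 0.5; (5) assign voxels claimed by
#' both re-binarized clusters to the cluster with the nearer center of mass
#' (Euclidean, mm). The anterior (lower y centroid) ROI is Broca-like, the
#' posterior Wernicke-like.
#'
#' @param meta A `meta_map` (or plain Z 3D array plus `voxel_size_mm`).
#' @param z_threshold Z threshold (default 3.7).
#' @param smooth1_fwhm,smooth2_fwhm FWHM in mm of the pre-threshold and
#'   cluster smooths.
#' @param connectivity Cluster connectivity (26 or 6).
#' @param voxel_size_mm Voxel size when `meta` is a plain array.
#' @param rebinarize_at Threshold for step-4 re-binarization.
#' @return Object of class `language_rois`: `broca_mask`, `wernicke_mask`
#'   (disjoint logical volumes), `provenance` (thresholds, cluster census,
#'   centers of mass), `tanh_map`.
#' @export
build_language_rois <- function(meta, z_threshold = 3.7, smooth1_fwhm = 1,
                                smooth2_fwhm = 3, connectivity = 26,
                                voxel_size_mm = NULL, rebinarize_at = 0.5) {
  if (inherits(meta, "meta_map")) {
    z <- meta$zvolume
    voxel_size_mm <- voxel_size_mm %||% meta$voxel_size_mm
  } else {
    z <- meta
    voxel_size_mm <- voxel_size_mm %||% 1
  }
  grid <- dim(z)

  # step 1: light smooth
  z1 <- spatial_smooth(z, smooth1_fwhm, voxel_size_mm)
  # step 2: tanh probability map for positive Z; threshold in Z units
  pmap <- array(0, grid)
  pos <- z1 > 0
  pmap[pos] <- tanh(z1[pos])
  supra <- z1 > z_threshold
  # step 3: left hemisphere, two largest clusters
  left <- slice.index(supra, 1) <= grid[1] / 2
  supra <- supra & left
  cc <- connected_components(supra, connectivity)
  census <- sort(cc$sizes, decreasing = TRUE)
  if (length(cc$sizes) < 2)
    stopf("insufficient clusters: %d supra-threshold cluster(s) found (sizes: %s)",
          length(cc$sizes),
          if (length(census)) paste(census, collapse = ", ") else "none")
  ord <- order(cc$sizes, decreasing = TRUE)
  if (length(ord) >= 3 && cc$sizes[ord[2]] == cc$sizes[ord[3]]) {
    # tie for the 2nd-largest slot: prefer the cluster with larger peak z
    tied <- ord[-1][cc$sizes[ord[-1]] == cc$sizes[ord[2]]]
    peaks <- vapply(tied, function(l) max(z1[cc$labels == l]), 0)
    ord <- c(ord[1], tied[order(-peaks)], setdiff(ord[-1], tied))
  }
  keep <- ord[1:2]
  # steps 4-5: per-cluster indicator smooth, re-binarize, resolve overlap
  masks <- lapply(keep, function(l) {
    ind <- array(as.numeric(cc$labels == l), grid)
    spatial_smooth(ind, smooth2_fwhm, voxel_size_mm) >= rebinarize_at
  })
  coms <- lapply(masks, center_of_mass, voxel_size_mm = voxel_size_mm)
  overlap <- masks[[1]] & masks[[2]]
  if (any(overlap)) {
    ov <- which(overlap)
    coords <- arrayInd(ov, grid) * voxel_size_mm
    d1 <- rowSums(sweep(coords, 2, coms[[1]])^2)
    d2 <- rowSums(sweep(coords, 2, coms[[2]])^2)
    masks[[1]][ov[d1 > d2]] <- FALSE
    masks[[2]][ov[d1 <= d2]] <- FALSE
  }
  # name by anterior/posterior centroid (anterior = lower y)
  coms <- lapply(masks, center_of_mass, voxel_size_mm = voxel_size_mm)
  if (coms[[1]][2] > coms[[2]][2]) {
    masks <- rev(masks)
    coms <- rev(coms)
    keep <- rev(keep)
  }
  if (any(masks[[1]] & masks[[2]]))
    stopf("internal error: ROIs are not disjoint")
  structure(list(broca_mask = masks[[1]],
                 wernicke_mask = masks[[2]],
                 provenance = list(z_threshold = z_threshold,
                                   smooth1_fwhm = smooth1_fwhm,
                                   smooth2_fwhm = smooth2_fwhm,
                                   connectivity = connectivity,
                                   rebinarize_at = rebinarize_at,
                                   cluster_census = census,
                                   kept_labels = keep,
                                   broca_com_mm = coms[[1]],
                                   wernicke_com_mm = coms[[2]]),
                 tanh_map = pmap),
            class = "language_rois")
}

#' @export
print.language_rois <- function(x, ...) {
  cat(sprintf("Language ROIs: Broca-like %d voxels, Wernicke-like %d voxels (Z > %g, %d-connectivity)\n",
              sum(x$broca_mask), sum(x$wernicke_mask),
              x$provenance$z_threshold, x$provenance$connectivity))
  invisible(x)
}
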
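# Thin NIfTI-1 wrappers (RNifti backend) for pipeline artifacts.

#' Write a volume to NIfTI-1
#'
#' @param arr 3D or 4D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm Isotropic voxel size written into the header.
#' @param tr Frame time in seconds for 4D data.
#' @return The path, invisibly.
#' @export
write_volume_nifti <- function(arr, path, voxel_size_mm = 3, tr = NULL) {
  pd <- rep(voxel_size_mm, 3)
  if (length(dim(arr)) == 4) pd <- c(pd, tr %||% 1)
  img <- RNifti::asNifti(arr, pixdim = pd)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume as a plain array
#'
#' @param path Input path.
#' @return Numeric array with attribute `voxel_size_mm`.
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_size_mm") <- RNifti::pixdim(img)[1]
  out
}

#' Write a censor mask as single-column text
#'
#' One 0/1 per frame (1 = kept), the plain-text exchange format for frame
#' censoring.
#'
#' @param censor A `censor_mask`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_censor_text <- function(censor, path) {
  writeLines(as.character(as.integer(censor$keep)), path)
  invisible(path)
}
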
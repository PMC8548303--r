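#' Voxel volume of CT intensities
#'
#' A 3D grid of Hounsfield units with per-axis spacing and origin in mm.
#' The canonical frame is X left-to-right, Y front-to-back, Z feet-to-head;
#' note this X runs opposite to the DICOM LPS convention, so the loader
#' offers a flip.
#'
#' @param intensities 3D numeric array of HU values.
#' @param spacing per-axis voxel size (mm), length 3.
#' @param origin position of the centre of voxel (1,1,1) in mm.
#' @return a `ctma_volume`.
#' @export
voxel_volume <- function(intensities, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0)) {
  if (length(dim(intensities)) != 3L) stop("intensities must be 3D")
  if (any(dim(intensities) == 0L)) stop("empty intensity grid")
  if (any(spacing <= 0)) stop("spacing must be positive on all axes")
  if (!all(is.finite(intensities))) stop("non-finite HU values")
  structure(list(intensities = intensities, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "ctma_volume")
}

#' @export
print.ctma_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("ctma_volume %d x %d x %d, spacing (%.2f, %.2f, %.2f) mm, HU [%d, %d]\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              round(min(x$intensities)), round(max(x$intensities))))
  invisible(x)
}

# voxel index (1-based, may be fractional) of an mm position
mm_to_index <- function(volume, pos) {
  (as.numeric(pos) - volume$origin) / volume$spacing + 1
}

index_to_mm <- function(volume, idx) {
  sweep(sweep(idx - 1, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

#' Read a CT volume from NIfTI
#'
#' Loads a NIfTI file into a [voxel_volume()].  With
#' `lps_to_canonical = TRUE` the first axis is flipped so that X increases
#' left-to-right in the canonical frame (DICOM LPS stores X right-to-left).
#'
#' @param path NIfTI file.
#' @param lps_to_canonical flip the X axis from LPS into the canonical
#'   frame.
#' @return a `ctma_volume`.
#' @export
read_volume_nifti <- function(path, lps_to_canonical = FALSE) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("package RNifti is required to read NIfTI volumes")
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  spacing <- as.numeric(RNifti::pixdim(img))[1:3]
  if (lps_to_canonical) arr <- arr[dim(arr)[1]:1, , , drop = FALSE]
  voxel_volume(arr, spacing = spacing, origin = c(0, 0, 0))
}

#' Write a bone mask as NIfTI
#' @param mask a `ctma_mask`.
#' @param path output path.
#' @export
write_mask_nifti <- function(mask, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("package RNifti is required to write NIfTI volumes")
  img <- RNifti::asNifti(array(as.integer(mask$mask), dim(mask$mask)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}
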
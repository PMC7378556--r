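#' 3D scalar volume with voxel spacing
#'
#' A `volume_image` holds a 3D array of scalar intensities (arbitrary MR
#' units) together with the voxel spacing in millimetres per axis.  All
#' values must be finite, spacing strictly positive and every axis at least
#' 8 voxels long, so that texture neighbourhoods and histogram mode
#' detection are meaningful.
#'
#' @param voxels 3D numeric array of intensities.
#' @param spacing Numeric length-3 vector, mm per axis (default 1 mm
#'   isotropic, the grid the pipeline assumes inputs were resampled to).
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(voxels, spacing = c(1, 1, 1)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  if (any(dim(voxels) < 8L))
    stop("each axis of a volume_image must have length >= 8")
  if (!all(is.finite(voxels)))
    stop("volume_image voxels must all be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive numbers")
  structure(list(voxels = voxels, spacing = spacing), class = "volume_image")
}

#' Binary mask on the same grid as a volume
#'
#' @param voxels 3D array coercible to logical/0-1.
#' @param spacing Numeric length-3 spacing in mm.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  v <- array(as.integer(voxels != 0), dim = dim(voxels))
  if (anyNA(v))
    stop("binary_mask voxels must not contain NA")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive numbers")
  structure(list(voxels = v, spacing = spacing), class = "binary_mask")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, spacing ", paste(x$spacing, collapse = "x"), " mm, range [",
      format(min(x$voxels)), ", ", format(max(x$voxels)), "]\n", sep = "")
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  cat("<binary_mask> ", paste(dim(x$voxels), collapse = " x "),
      " voxels, ", sum(x$voxels), " foreground\n", sep = "")
  invisible(x)
}

stopifnot_same_grid <- function(img, mask) {
  if (!identical(dim(img$voxels), dim(mask$voxels)))
    stop("image and mask are not on the same grid")
  invisible(TRUE)
}

#' Number of foreground voxels in a mask
#' @param mask A `binary_mask`.
#' @return Integer count.
#' @export
mask_volume <- function(mask) sum(mask$voxels)

#' Intensities of the voxels selected by a mask
#' @param img A `volume_image`.
#' @param mask A `binary_mask` on the same grid.
#' @return Numeric vector of in-mask intensities.
#' @export
mask_values <- function(img, mask) {
  stopifnot_same_grid(img, mask)
  img$voxels[mask$voxels == 1L]
}

#' Read / write volumes as NIfTI
#'
#' Thin wrappers over \pkg{RNifti} preserving the spacing of the
#' `volume_image` / `binary_mask` containers.
#'
#' @param x A `volume_image` or `binary_mask`.
#' @param path File path ending in `.nii` or `.nii.gz`.
#' @return `write_nifti` returns `path` invisibly; `read_volume` /
#'   `read_mask` return the corresponding container.
#' @export
write_nifti <- function(x, path) {
  img <- RNifti::asNifti(x$voxels, pixdim = x$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti
#' @export
read_volume <- function(path) {
  nii <- RNifti::readNifti(path)
  volume_image(array(as.numeric(nii), dim = dim(nii)),
               spacing = RNifti::pixdim(nii)[seq_len(3)])
}

#' @rdname write_nifti
#' @export
read_mask <- function(path) {
  nii <- RNifti::readNifti(path)
  binary_mask(array(as.numeric(nii), dim = dim(nii)),
              spacing = RNifti::pixdim(nii)[seq_len(3)])
}
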
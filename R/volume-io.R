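#' Image volumes and region-of-interest masks
#'
#' An `image_volume` is a 3D array of intensities together with its voxel
#' spacing in millimetres; an `roi_mask` is a binary 3D array on the same
#' grid marking the tumor region of interest. Both are plain lists so that
#' downstream feature code can treat them as arrays plus metadata.
#'
#' @param intensities 3D numeric array.
#' @param spacing_mm positive numeric triple, voxel edge lengths in mm.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(intensities, spacing_mm = c(1, 1, 1)) {
  intensities <- as.array(intensities)
  if (length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  if (!all(is.finite(intensities)))
    stop("intensities must be finite")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be a positive triple")
  structure(list(intensities = intensities, spacing_mm = spacing_mm),
            class = "image_volume")
}

#' @param values 3D array coerced to binary (> 0.5 is foreground).
#' @rdname image_volume
#' @export
roi_mask <- function(values, spacing_mm = c(1, 1, 1)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("mask values must be a 3D array")
  bin <- array(as.integer(values > 0.5), dim(values))
  if (sum(bin) == 0L)
    stop("mask is empty: no foreground voxels")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("spacing_mm must be a positive triple")
  structure(list(values = bin, spacing_mm = spacing_mm),
            class = "roi_mask")
}

#' Read a volume or mask from NIfTI
#'
#' Voxel spacing is taken from the NIfTI header (`pixdim`). Masks are
#' binarized at 0.5 and must contain at least one foreground voxel; if
#' `volume` is supplied the mask grid must match the volume grid.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @return `read_volume()` an `image_volume`; `read_mask()` an `roi_mask`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  image_volume(array(as.numeric(img), dim(img)[1:3]),
               RNifti::pixdim(img)[1:3])
}

#' @param volume optional paired `image_volume` used to validate the grid.
#' @rdname read_volume
#' @export
read_mask <- function(path, volume = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  vals <- array(as.numeric(img), dim(img)[1:3])
  if (!is.null(volume) && !all(dim(vals) == dim(volume$intensities)))
    stop("mask grid ", paste(dim(vals), collapse = "x"),
         " does not match volume grid ",
         paste(dim(volume$intensities), collapse = "x"))
  roi_mask(vals, RNifti::pixdim(img)[1:3])
}

#' Write a volume or mask to NIfTI
#'
#' @param x an `image_volume` or `roi_mask`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  arr <- if (inherits(x, "roi_mask")) x$values else x$intensities
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- x$spacing_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
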
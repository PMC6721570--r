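#' Resample a volume or mask to isotropic spacing
#'
#' Multi-site MR data come at heterogeneous voxel sizes; texture features
#' are only comparable on a common grid, so every volume is resampled to
#' isotropic 1 mm voxels before feature extraction. Images are interpolated
#' trilinearly; masks nearest-neighbour, which preserves binarity.
#'
#' The output grid has `round(dim * spacing / target)` voxels per axis and
#' voxel centres aligned with the first input voxel centre.
#'
#' @param x an `image_volume` or `roi_mask`.
#' @param target_spacing target isotropic voxel edge in mm (default 1).
#' @return resampled object of the same class.
#' @export
resample_isotropic <- function(x, target_spacing = 1.0) {
  if (length(target_spacing) != 1L || target_spacing <= 0)
    stop("target_spacing must be a single positive number")
  is_mask <- inherits(x, "roi_mask")
  arr <- if (is_mask) x$values else x$intensities
  sp <- x$spacing_mm
  old_dim <- dim(arr)
  new_dim <- pmax(1L, as.integer(round(old_dim * sp / target_spacing)))

  # physical coordinates of new voxel centres, in input voxel index units
  idx <- lapply(1:3, function(a)
    ((seq_len(new_dim[a]) - 1) * target_spacing) / sp[a] + 1)

  if (is_mask) {
    near <- lapply(1:3, function(a)
      pmin(pmax(as.integer(round(idx[[a]])), 1L), old_dim[a]))
    out <- arr[near[[1]], near[[2]], near[[3]], drop = FALSE]
    dim(out) <- new_dim
    return(roi_mask(out, rep(target_spacing, 3)))
  }

  lo <- lapply(1:3, function(a)
    pmin(pmax(floor(idx[[a]]), 1), old_dim[a]))
  hi <- lapply(1:3, function(a) pmin(lo[[a]] + 1, old_dim[a]))
  fr <- lapply(1:3, function(a) idx[[a]] - lo[[a]])

  out <- array(0, new_dim)
  # accumulate the 8 trilinear corner contributions, vectorized per corner
  for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
    ix <- if (cx) hi[[1]] else lo[[1]]
    iy <- if (cy) hi[[2]] else lo[[2]]
    iz <- if (cz) hi[[3]] else lo[[3]]
    wx <- if (cx) fr[[1]] else 1 - fr[[1]]
    wy <- if (cy) fr[[2]] else 1 - fr[[2]]
    wz <- if (cz) fr[[3]] else 1 - fr[[3]]
    w <- outer(outer(wx, wy), wz)
    out <- out + w * arr[ix, iy, iz, drop = FALSE]
  }
  image_volume(out, rep(target_spacing, 3))
}

#' Rescale intensities to the unit interval
#'
#' Per-volume min–max normalization: `(x - min) / (max - min)` over the
#' whole volume. A constant volume maps to all zeros (defined convention
#' avoiding division by zero).
#'
#' @param volume an `image_volume`.
#' @return normalized `image_volume` with intensities in `[0, 1]`.
#' @export
normalize_intensity <- function(volume) {
  arr <- volume$intensities
  rng <- range(arr)
  if (rng[2] > rng[1]) {
    arr <- (arr - rng[1]) / (rng[2] - rng[1])
  } else {
    arr[] <- 0
  }
  image_volume(arr, volume$spacing_mm)
}

#' Quantize ROI intensities to discrete gray levels
#'
#' Texture matrices are computed on a small number of gray levels. In-mask
#' intensities are binned uniformly between the in-mask minimum and maximum
#' into `n_levels` equal-width bins:
#' `level = 1 + floor(n_levels * (x - min) / (max - min))`, with the
#' maximum clipped into the top bin. Out-of-mask voxels are level 0. A
#' constant ROI maps entirely to level 1.
#'
#' @param volume an `image_volume`.
#' @param mask an `roi_mask` on the same grid.
#' @param n_levels number of gray levels (default 32).
#' @return a `quantized_roi`: list with integer array `levels` (0 outside
#'   the mask), `n_levels`, and the mask `spacing_mm`.
#' @export
quantize_gray_levels <- function(volume, mask, n_levels = 32L) {
  if (!all(dim(volume$intensities) == dim(mask$values)))
    stop("volume and mask grids differ")
  n_levels <- as.integer(n_levels)
  if (n_levels < 2L) stop("n_levels must be at least 2")
  inmask <- mask$values == 1L
  x <- volume$intensities[inmask]
  rng <- range(x)
  lev <- array(0L, dim(mask$values))
  if (rng[2] > rng[1]) {
    q <- 1L + as.integer(floor(n_levels * (x - rng[1]) / (rng[2] - rng[1])))
    q[q > n_levels] <- n_levels
  } else {
    q <- rep(1L, length(x))
  }
  lev[inmask] <- q
  structure(list(levels = lev, n_levels = n_levels,
                 spacing_mm = mask$spacing_mm),
            class = "quantized_roi")
}
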
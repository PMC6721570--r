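#' Morphological shape features of a tumor mask
#'
#' Four descriptors of lesion geometry, computed on the (isotropically
#' resampled) binary mask:
#' * `shape_volume_mm3` — voxel count times voxel volume;
#' * `shape_surface_area_mm2` — total area of exposed voxel faces
#'   (boundary-face counting);
#' * `shape_fractal_dimension` — box-counting dimension: least-squares
#'   slope of log N(s) against log(1/s) over dyadic box sizes
#'   s in {1, 2, 4, 8, 16} (restricted to sizes not exceeding the mask
#'   bounding box);
#' * `shape_porosity` — fraction of the hole-filled mask occupied by
#'   internal cavities: `(filled - mask) / filled` voxel counts, where
#'   `filled` closes cavities by flood-filling the background from the
#'   grid border (6-connectivity).
#'
#' @param mask an `roi_mask`.
#' @return named numeric vector of the four shape features.
#' @export
shape_features <- function(mask) {
  m <- mask$values == 1L
  sp <- mask$spacing_mm
  nvox <- sum(m)
  if (nvox == 0L) stop("empty mask")

  vol <- nvox * prod(sp)

  # exposed faces: mask voxel whose neighbour along an axis is background
  # (or out of grid); face area is the product of the other two spacings
  d <- dim(m)
  face_area <- c(sp[2] * sp[3], sp[1] * sp[3], sp[1] * sp[2])
  surf <- 0
  for (ax in 1:3) {
    pad <- array(FALSE, d + 2 * (seq_len(3) == ax))
    idx <- lapply(1:3, function(a)
      if (a == ax) seq_len(d[a]) + 1L else seq_len(d[a]))
    pad[idx[[1]], idx[[2]], idx[[3]]] <- m
    shift_lo <- do.call(`[`, c(list(pad), lapply(1:3, function(a)
      if (a == ax) seq_len(d[a]) else seq_len(d[a])), list(drop = FALSE)))
    shift_hi <- do.call(`[`, c(list(pad), lapply(1:3, function(a)
      if (a == ax) seq_len(d[a]) + 2L else seq_len(d[a])), list(drop = FALSE)))
    surf <- surf + face_area[ax] * (sum(m & !shift_lo) + sum(m & !shift_hi))
  }

  fd <- box_counting_dimension(m)

  filled <- fill_holes(m)
  nfill <- sum(filled)
  poros <- (nfill - nvox) / nfill

  c(shape_volume_mm3 = vol, shape_surface_area_mm2 = surf,
    shape_fractal_dimension = fd, shape_porosity = poros)
}

# box-counting dimension over dyadic box sizes on the cropped bounding box
box_counting_dimension <- function(m) {
  bb <- apply(which(m, arr.ind = TRUE), 2, range)
  crop <- m[bb[1, 1]:bb[2, 1], bb[1, 2]:bb[2, 2], bb[1, 3]:bb[2, 3],
            drop = FALSE]
  d <- dim(crop)
  sizes <- c(1L, 2L, 4L, 8L, 16L)
  sizes <- sizes[sizes <= max(d)]
  if (length(sizes) < 2L) sizes <- c(1L, 2L)
  counts <- vapply(sizes, function(s) {
    nb <- ceiling(d / s)
    bx <- (seq_len(d[1]) - 1L) %/% s
    by <- (seq_len(d[2]) - 1L) %/% s
    bz <- (seq_len(d[3]) - 1L) %/% s
    id <- bx[slice.index(crop, 1)] +
      nb[1] * by[slice.index(crop, 2)] +
      nb[1] * nb[2] * bz[slice.index(crop, 3)]
    length(unique(id[crop]))
  }, numeric(1))
  stats::coef(stats::lm(log(counts) ~ log(1 / sizes)))[[2]]
}

# fill internal cavities: background voxels unreachable from the grid
# border by 6-connected flood fill are holes and get merged into the mask
fill_holes <- function(m) {
  d <- dim(m)
  bg <- !m
  outside <- array(FALSE, d)
  # seed with all background voxels on the grid border
  outside[c(1, d[1]), , ] <- bg[c(1, d[1]), , ]
  outside[, c(1, d[2]), ] <- outside[, c(1, d[2]), ] | bg[, c(1, d[2]), ]
  outside[, , c(1, d[3])] <- outside[, , c(1, d[3])] | bg[, , c(1, d[3])]
  repeat {
    grown <- outside
    grown[-1, , ] <- grown[-1, , ] | outside[-d[1], , ]
    grown[-d[1], , ] <- grown[-d[1], , ] | outside[-1, , ]
    grown[, -1, ] <- grown[, -1, ] | outside[, -d[2], ]
    grown[, -d[2], ] <- grown[, -d[2], ] | outside[, -1, ]
    grown[, , -1] <- grown[, , -1] | outside[, , -d[3]]
    grown[, , -d[3]] <- grown[, , -d[3]] | outside[, , -1]
    grown <- grown & bg
    if (identical(grown, outside)) break
    outside <- grown
  }
  m | (bg & !outside)
}
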
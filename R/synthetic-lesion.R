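#' Generate a textured ellipsoidal lesion phantom
#'
#' Produces a 3D volume and binary mask emulating a contrast-enhancing
#' tumor: an ellipsoid (random axis ratios around `radius_mm`, random
#' orientation-free axis-aligned shape) centred in the field of view,
#' filled with a Gaussian random field whose correlation length is
#' `texture_scale_mm`, rescaled into (0, 1]; background is low-amplitude
#' uniform noise. The correlation length is the texture dial: long
#' correlation lengths give smooth, coarse texture (high NGTDM
#' coarseness), short ones give busy, high-contrast texture. Fully
#' deterministic given `seed`.
#'
#' @param shape voxel grid dimensions (triple).
#' @param spacing voxel spacing in mm (triple).
#' @param radius_mm nominal lesion radius in mm; must fit in the grid.
#' @param texture_scale_mm Gaussian-field correlation length in mm;
#'   `Inf` yields a uniform lesion interior.
#' @param seed integer RNG seed.
#' @return list with `volume` (an `image_volume`) and `mask` (an
#'   `roi_mask`).
#' @export
generate_lesion <- function(shape, spacing = c(1, 1, 1), radius_mm = 8,
                            texture_scale_mm = 3, seed = 1L) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  fov <- shape * spacing
  if (any(2 * radius_mm > fov))
    stop("lesion radius ", radius_mm, " mm does not fit in field of view ",
         paste(round(fov, 1), collapse = "x"), " mm")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # ellipsoid semi-axes: radius perturbed per axis, capped to fit
  semi <- radius_mm * stats::runif(3, 0.75, 1.25)
  semi <- pmin(semi, fov / 2 - spacing)
  ctr <- fov / 2
  cx <- ((seq_len(shape[1]) - 0.5) * spacing[1] - ctr[1]) / semi[1]
  cy <- ((seq_len(shape[2]) - 0.5) * spacing[2] - ctr[2]) / semi[2]
  cz <- ((seq_len(shape[3]) - 0.5) * spacing[3] - ctr[3]) / semi[3]
  r2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  mvals <- r2 <= 1

  vol <- array(stats::runif(prod(shape), 0, 0.08), shape)  # background noise
  inside <- which(mvals)
  if (is.finite(texture_scale_mm) && texture_scale_mm > 0) {
    field <- gaussian_random_field(shape, texture_scale_mm / spacing)
    f <- field[inside]
    rng <- range(f)
    if (rng[2] > rng[1]) {
      # map into (0.1, 1]: strictly positive lesion intensities
      vol[inside] <- 0.1 + 0.9 * (f - rng[1]) / (rng[2] - rng[1])
    } else {
      vol[inside] <- 0.8
    }
  } else {
    vol[inside] <- 0.8  # infinite correlation length: uniform interior
  }

  list(volume = image_volume(vol, spacing),
       mask = roi_mask(array(as.integer(mvals), shape), spacing))
}

# smoothed white noise via FFT: multiply the noise spectrum by the
# spectrum of a wrapped Gaussian kernel with per-axis sd sigma_vox,
# then standardize to unit variance
gaussian_random_field <- function(shape, sigma_vox) {
  noise <- array(stats::rnorm(prod(shape)), shape)
  sigma_vox <- pmax(sigma_vox, 1e-6)
  kern1 <- lapply(1:3, function(a) {
    x <- seq_len(shape[a]) - 1
    x <- pmin(x, shape[a] - x)  # wrapped distances
    stats::dnorm(x, sd = sigma_vox[a])
  })
  kern <- outer(outer(kern1[[1]], kern1[[2]]), kern1[[3]])
  kern <- kern / sum(kern)
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(kern),
                      inverse = TRUE)) / prod(shape)
  (sm - mean(sm)) / stats::sd(sm)
}

# save/restore the global RNG state so seeded generators do not disturb
# the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
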
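#' First-order intensity features of an ROI
#'
#' Six statistics of the in-mask intensity distribution: mean, variance,
#' skewness, kurtosis, energy and entropy. Moments are population-form
#' (variance with divisor n, kurtosis non-excess); energy is the mean
#' square intensity; entropy is Shannon entropy in bits of a 32-bin
#' equal-width histogram spanning the in-mask intensity range (same
#' binning rule as gray-level quantization). A constant ROI has variance,
#' skewness, kurtosis and entropy 0 by convention.
#'
#' @param volume an `image_volume`.
#' @param mask an `roi_mask` on the same grid.
#' @param n_bins histogram bins for the entropy (default 32).
#' @return named numeric vector of the six intensity features.
#' @export
intensity_features <- function(volume, mask, n_bins = 32L) {
  if (!all(dim(volume$intensities) == dim(mask$values)))
    stop("volume and mask grids differ")
  x <- volume$intensities[mask$values == 1L]
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  if (m2 > 0) {
    skew <- mean((x - mu)^3) / m2^1.5
    kurt <- mean((x - mu)^4) / m2^2
  } else {
    skew <- 0
    kurt <- 0
  }
  energy <- mean(x^2)

  rng <- range(x)
  if (rng[2] > rng[1]) {
    bin <- 1L + floor(n_bins * (x - rng[1]) / (rng[2] - rng[1]))
    bin[bin > n_bins] <- n_bins
    p <- tabulate(bin, n_bins) / n
    p <- p[p > 0]
    entropy <- -sum(p * log2(p))
  } else {
    entropy <- 0
  }

  c(intensity_mean = mu, intensity_variance = m2,
    intensity_skewness = skew, intensity_kurtosis = kurt,
    intensity_energy = energy, intensity_entropy = entropy)
}
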
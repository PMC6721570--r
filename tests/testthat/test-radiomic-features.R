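test_that("shape features are exact on a solid cube", {
  m <- array(0L, c(14, 14, 14))
  m[3:12, 3:12, 3:12] <- 1L  # 10x10x10 cube at 1 mm
  sf <- shape_features(roi_mask(m))
  expect_equal(unname(sf["shape_volume_mm3"]), 1000)
  expect_equal(unname(sf["shape_surface_area_mm2"]), 600)
  expect_equal(unname(sf["shape_porosity"]), 0)
})

test_that("porosity detects an internal cavity", {
  m <- array(0L, c(12, 12, 12))
  m[2:11, 2:11, 2:11] <- 1L
  m[5:7, 5:7, 5:7] <- 0L  # 27-voxel hole, fully enclosed
  sf <- shape_features(roi_mask(m))
  expect_equal(unname(sf["shape_porosity"]), 27 / 1000)
  # an open notch touching the surface is not a hole
  m2 <- array(0L, c(12, 12, 12))
  m2[2:11, 2:11, 2:11] <- 1L
  m2[5:7, 5:7, 2:7] <- 0L
  expect_equal(unname(shape_features(roi_mask(m2))["shape_porosity"]), 0)
})

test_that("box-counting dimension of a solid cube approaches 3", {
  m <- array(0L, c(34, 34, 34))
  m[2:33, 2:33, 2:33] <- 1L  # 32^3 cube
  fd <- unname(shape_features(roi_mask(m))["shape_fractal_dimension"])
  expect_gte(fd, 2.8)
  expect_lte(fd, 3.0)
})

test_that("intensity features match direct recomputation", {
  # uniform occupancy over 32 bins -> entropy = 5 bits
  vals <- rep(seq(0, 1, length.out = 32), each = 2)
  vol <- image_volume(array(vals, c(4, 4, 4)))
  msk <- roi_mask(array(1L, c(4, 4, 4)))
  expect_equal(unname(intensity_features(vol, msk)["intensity_entropy"]), 5)

  # symmetric two-point distribution has zero skewness
  v2 <- image_volume(array(rep(c(0.2, 0.8), 32), c(4, 4, 4)))
  expect_equal(unname(intensity_features(v2, msk)["intensity_skewness"]), 0)

  # random ROI: all six statistics match naive formulas
  set.seed(11)
  d <- c(10, 10, 10)
  vol <- image_volume(array(stats::rnorm(1000), d))
  msk <- roi_mask(array(1L, d))
  f <- intensity_features(vol, msk)
  x <- as.numeric(vol$intensities)
  mu <- sum(x) / 1000
  m2 <- sum((x - mu)^2) / 1000
  expect_equal(unname(f["intensity_mean"]), mu, tolerance = 1e-10)
  expect_equal(unname(f["intensity_variance"]), m2, tolerance = 1e-10)
  expect_equal(unname(f["intensity_skewness"]),
               sum((x - mu)^3) / 1000 / m2^1.5, tolerance = 1e-10)
  expect_equal(unname(f["intensity_kurtosis"]),
               sum((x - mu)^4) / 1000 / m2^2, tolerance = 1e-10)
  expect_equal(unname(f["intensity_energy"]), sum(x^2) / 1000,
               tolerance = 1e-10)
  bin <- pmin(1L + floor(32 * (x - min(x)) / diff(range(x))), 32L)
  p <- tabulate(bin, 32) / 1000
  p <- p[p > 0]
  expect_equal(unname(f["intensity_entropy"]), -sum(p * log2(p)),
               tolerance = 1e-10)
})

test_that("GLCM micro-examples match hand enumeration", {
  # single-slice [[1,1],[2,2]] along the in-slice x direction only
  q <- structure(list(levels = array(c(1L, 2L, 1L, 2L), c(2, 2, 1)),
                      n_levels = 2L, spacing_mm = c(1, 1, 1)),
                 class = "quantized_roi")
  m <- compute_glcm(q, directions = matrix(c(0, 1, 0), 1))
  expect_equal(m$p, matrix(c(0.5, 0, 0, 0.5), 2))
  f <- glcm_features(m)
  expect_equal(unname(f["glcm_autocorrelation"]), 2.5)
  expect_equal(unname(f["glcm_sum_of_squares_variance"]), 0.25)

  # constant ROI: p(1,1) = 1, contrast 0, autocorrelation 1, max prob 1
  qc <- structure(list(levels = array(1L, c(3, 3, 3)), n_levels = 4L,
                       spacing_mm = c(1, 1, 1)), class = "quantized_roi")
  mc <- compute_glcm(qc)
  expect_equal(mc$p[1, 1], 1)
  fc <- glcm_features(mc)
  expect_equal(unname(fc[c("glcm_contrast", "glcm_autocorrelation",
                           "glcm_maximum_probability")]), c(0, 1, 1))
})

test_that("GLCM normalization, symmetry and feature bounds hold", {
  for (seed in 1:5) {
    q <- random_quantized_roi(seed)
    m <- compute_glcm(q)
    expect_equal(sum(m$p), 1, tolerance = 1e-12)
    expect_equal(m$p, t(m$p), tolerance = 1e-12)
    f <- glcm_features(m)
    expect_gte(f[["glcm_correlation"]], -1)
    expect_lte(f[["glcm_correlation"]], 1)
    expect_gt(f[["glcm_energy"]], 0)
    expect_lte(f[["glcm_energy"]], 1)
  }
})

test_that("GLSZM micro-examples match hand enumeration", {
  # [[1,1],[2,3]]: zones (1, size 2), (2, 1), (3, 1)
  q <- structure(list(levels = array(c(1L, 2L, 1L, 3L), c(2, 2, 1)),
                      n_levels = 3L, spacing_mm = c(1, 1, 1)),
                 class = "quantized_roi")
  z <- compute_glszm(q)
  expect_equal(z$n_zones, 3L)
  expect_equal(z$s[1, 2], 1L)
  expect_equal(z$s[2, 1], 1L)
  expect_equal(z$s[3, 1], 1L)
  f <- glszm_features(z)
  expect_equal(unname(f["glszm_small_zone_high_gray_emphasis"]),
               (1 / 4 + 4 + 9) / 3, tolerance = 1e-6)
  expect_equal(unname(f["glszm_large_zone_low_gray_emphasis"]),
               (4 + 1 / 4 + 1 / 9) / 3, tolerance = 1e-4)

  # one-voxel ROI at level i: single zone, SZHGE = i^2
  for (i in c(2L, 5L)) {
    lv <- array(0L, c(3, 3, 3)); lv[2, 2, 2] <- i
    q1 <- structure(list(levels = lv, n_levels = 6L,
                         spacing_mm = c(1, 1, 1)), class = "quantized_roi")
    z1 <- compute_glszm(q1)
    expect_equal(z1$n_zones, 1L)
    expect_equal(
      unname(glszm_features(z1)["glszm_small_zone_high_gray_emphasis"]),
      i^2)
  }
})

test_that("GLSZM conserves voxel mass on random ROIs", {
  for (seed in 1:8) {
    q <- random_quantized_roi(seed, p_mask = runif(1, 0.2, 0.9))
    z <- compute_glszm(q)
    sizes <- matrix(seq_len(ncol(z$s)), nrow(z$s), ncol(z$s), byrow = TRUE)
    expect_equal(sum(z$s * sizes), sum(q$levels > 0L))
  }
})

test_that("NGTDM follows the masked complete-neighbourhood rule", {
  # 3x3 patch in a single-slice grid: only the centre voxel has every
  # in-grid neighbour inside the mask
  lev <- array(0L, c(5, 5, 1))
  lev[2:4, 2:4, 1] <- 1L
  lev[3, 3, 1] <- 2L
  q <- structure(list(levels = lev, n_levels = 2L, spacing_mm = c(1, 1, 1)),
                 class = "quantized_roi")
  tm <- compute_ngtdm(q)
  expect_equal(tm$n_valid, 1L)
  expect_equal(tm$s, c(0, 1))  # |2 - mean(eight 1s)| = 1
  nf <- naive_ngtdm(q)
  expect_equal(tm$s, nf$s)
  expect_equal(tm$p, nf$p)
  expect_equal(ngtdm_features(tm), naive_ngtdm_features(nf),
               tolerance = 1e-12)

  # constant ROI: coarseness capped, contrast 0
  qc <- structure(list(levels = array(1L, c(4, 4, 4)), n_levels = 3L,
                       spacing_mm = c(1, 1, 1)), class = "quantized_roi")
  fc <- ngtdm_features(compute_ngtdm(qc))
  expect_equal(unname(fc["ngtdm_coarseness"]), 1e6)
  expect_equal(unname(fc["ngtdm_contrast"]), 0)
})

test_that("texture engines agree with brute-force oracles on random ROIs", {
  for (seed in 1:10) {
    q <- random_quantized_roi(seed, p_mask = runif(1, 0.3, 0.9))
    expect_equal(compute_glcm(q)$p, naive_glcm(q), tolerance = 1e-10)
    expect_equal(glcm_features(compute_glcm(q)),
                 naive_glcm_features(naive_glcm(q)), tolerance = 1e-8)
    expect_equal(glszm_features(compute_glszm(q)),
                 naive_glszm_features(q), tolerance = 1e-8)
    tm <- compute_ngtdm(q)
    nf <- naive_ngtdm(q)
    expect_equal(tm$s, nf$s, tolerance = 1e-10)
    expect_equal(ngtdm_features(tm), naive_ngtdm_features(nf),
                 tolerance = 1e-8)
    # busyness and complexity are non-negative by definition
    ff <- ngtdm_features(tm)
    expect_gte(ff[["ngtdm_busyness"]], 0)
    expect_gte(ff[["ngtdm_complexity"]], 0)
  }
})

test_that("extract_all returns 45 finite features, invariant to translation
           and affine intensity rescaling", {
  ls <- small_lesion(31)
  v <- extract_all(ls$volume, ls$mask)
  expect_length(v, 45L)
  expect_named(v, radiomic_feature_names())
  expect_true(all(is.finite(v)))

  # translate the lesion by 3 voxels inside a larger grid
  big <- array(0, c(28, 28, 28))
  bigm <- array(0L, c(28, 28, 28))
  big[1:20, 1:20, 1:20] <- ls$volume$intensities
  bigm[1:20, 1:20, 1:20] <- ls$mask$values
  shf <- array(0, c(28, 28, 28))
  shfm <- array(0L, c(28, 28, 28))
  shf[4:23, 4:23, 4:23] <- ls$volume$intensities
  shfm[4:23, 4:23, 4:23] <- ls$mask$values
  v1 <- extract_all(image_volume(big), roi_mask(bigm))
  v2 <- extract_all(image_volume(shf), roi_mask(shfm))
  expect_equal(v1, v2, tolerance = 1e-10)

  # scaling intensities before normalization changes nothing
  raw <- generate_lesion(c(20, 20, 20), radius_mm = 6,
                         texture_scale_mm = 2.5, seed = 31)
  v3 <- extract_all(normalize_intensity(raw$volume), raw$mask)
  scaled <- image_volume(10 * raw$volume$intensities + 3)
  v4 <- extract_all(normalize_intensity(scaled), raw$mask)
  expect_equal(v3, v4, tolerance = 1e-8)
})

test_that("texture scale drives coarseness up and contrast down", {
  # 20 lesions over the generator's correlation-length range; two seeds
  # per scale are averaged to tame single-lesion sampling noise
  scales <- seq(1, 6, length.out = 10)
  cc <- sapply(seq_along(scales), function(k) {
    v <- sapply(1:2, function(r) {
      ls <- generate_lesion(c(26, 26, 26), radius_mm = 10,
                            texture_scale_mm = scales[k],
                            seed = 700 + 10 * k + r)
      f <- extract_all(normalize_intensity(ls$volume), ls$mask)
      c(f[["ngtdm_coarseness"]], f[["glcm_contrast"]])
    })
    rowMeans(v)
  })
  expect_gt(stats::cor(scales, cc[1, ], method = "spearman"), 0.8)
  expect_lt(stats::cor(scales, cc[2, ], method = "spearman"), -0.8)
})
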
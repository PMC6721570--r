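#' Canonical roster of the 45 radiomic features
#'
#' The fixed, ordered feature names produced by [extract_all()]:
#' 4 shape + 6 intensity + 19 GLCM + 11 GLSZM + 5 NGTDM.
#'
#' @return character vector of length 45.
#' @export
radiomic_feature_names <- function() {
  c("shape_volume_mm3", "shape_surface_area_mm2",
    "shape_fractal_dimension", "shape_porosity",
    "intensity_mean", "intensity_variance", "intensity_skewness",
    "intensity_kurtosis", "intensity_energy", "intensity_entropy",
    "glcm_autocorrelation", "glcm_cluster_prominence",
    "glcm_cluster_shade", "glcm_cluster_tendency", "glcm_contrast",
    "glcm_correlation", "glcm_difference_entropy",
    "glcm_difference_variance", "glcm_dissimilarity", "glcm_energy",
    "glcm_entropy", "glcm_homogeneity", "glcm_imc1", "glcm_imc2",
    "glcm_maximum_probability", "glcm_sum_average", "glcm_sum_entropy",
    "glcm_sum_of_squares_variance", "glcm_inverse_difference",
    "glszm_small_zone_emphasis", "glszm_large_zone_emphasis",
    "glszm_gray_level_nonuniformity", "glszm_zone_size_nonuniformity",
    "glszm_zone_percentage", "glszm_low_gray_zone_emphasis",
    "glszm_high_gray_zone_emphasis", "glszm_small_zone_low_gray_emphasis",
    "glszm_small_zone_high_gray_emphasis",
    "glszm_large_zone_low_gray_emphasis",
    "glszm_large_zone_high_gray_emphasis",
    "ngtdm_coarseness", "ngtdm_contrast", "ngtdm_busyness",
    "ngtdm_complexity", "ngtdm_strength")
}

#' Extract the full 45-feature radiomic vector from an ROI
#'
#' Applies gray-level quantization (32 levels by default) and computes
#' all five feature families. Inputs are expected to be preprocessed:
#' resampled to isotropic spacing and intensity-normalized per volume.
#' Any non-finite feature value is an error rather than a silent NaN.
#'
#' @param volume an `image_volume` (preprocessed).
#' @param mask an `roi_mask` on the same grid.
#' @param n_levels gray levels for texture quantization (default 32).
#' @return named numeric vector of length 45, in canonical order.
#' @export
extract_all <- function(volume, mask, n_levels = 32L) {
  if (!all(dim(volume$intensities) == dim(mask$values)))
    stop("volume and mask grids differ")
  q <- quantize_gray_levels(volume, mask, n_levels)
  v <- c(shape_features(mask),
         intensity_features(volume, mask, n_bins = n_levels),
         glcm_features(compute_glcm(q)),
         glszm_features(compute_glszm(q)),
         ngtdm_features(compute_ngtdm(q)))
  v <- v[radiomic_feature_names()]
  if (any(!is.finite(v)))
    stop("non-finite radiomic feature(s): ",
         paste(names(v)[!is.finite(v)], collapse = ", "))
  v
}

#' Extract radiomic features for a cohort of volume/mask files
#'
#' Reads each volume/mask pair, resamples both to isotropic 1 mm,
#' normalizes intensities, and extracts the 45-feature vector. Patients
#' whose mask is missing or unreadable are dropped with a message.
#'
#' @param volume_paths,mask_paths parallel character vectors of file paths.
#' @param patient_ids patient identifiers (default names from paths).
#' @param n_levels gray levels for texture quantization.
#' @param target_spacing isotropic resampling target in mm.
#' @return data.frame with `patient_id` and the 45 canonical feature
#'   columns, one row per successfully processed patient.
#' @export
extract_cohort_features <- function(volume_paths, mask_paths,
                                    patient_ids = NULL, n_levels = 32L,
                                    target_spacing = 1.0) {
  stopifnot(length(volume_paths) == length(mask_paths))
  if (is.null(patient_ids))
    patient_ids <- sub("\\.nii(\\.gz)?$", "", basename(volume_paths))
  rows <- vector("list", length(volume_paths))
  dropped <- character(0)
  for (k in seq_along(volume_paths)) {
    feat <- tryCatch({
      vol <- read_volume(volume_paths[k])
      msk <- read_mask(mask_paths[k], volume = vol)
      vol <- resample_isotropic(vol, target_spacing)
      msk <- resample_isotropic(msk, target_spacing)
      extract_all(normalize_intensity(vol), msk, n_levels)
    }, error = function(e) e)
    if (inherits(feat, "error")) {
      dropped <- c(dropped, patient_ids[k])
      message("dropping patient ", patient_ids[k], ": ",
              conditionMessage(feat))
    } else {
      rows[[k]] <- feat
    }
  }
  keep <- !vapply(rows, is.null, logical(1))
  out <- as.data.frame(do.call(rbind, rows[keep]))
  out <- cbind(patient_id = patient_ids[keep], out)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
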
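#!/usr/bin/env Rscript
# Stage 2: radiomic feature extraction.
#
# Reads every volume/mask pair of the planted cohort from disk, resamples
# to isotropic 1 mm, normalizes intensities to [0, 1], quantizes the ROI
# to 32 gray levels and computes the 45-feature radiomic vector (4 shape,
# 6 intensity, 19 GLCM, 11 GLSZM, 5 NGTDM). This recomputes from the
# images what stage 1 cached in data_planted/features.csv; the two must
# agree, which is asserted here.

suppressPackageStartupMessages(library(radsurv))

clin <- read.csv("results/data_planted/clinical.csv")
vols <- file.path("results/data_planted",
                  sprintf("vol_%s.nii.gz", clin$patient_id))
masks <- file.path("results/data_planted",
                   sprintf("mask_%s.nii.gz", clin$patient_id))

message("extracting 45 radiomic features for ", nrow(clin), " patients...")
feats <- extract_cohort_features(vols, masks, patient_ids = clin$patient_id)
write.csv(feats, "results/features.csv", row.names = FALSE)

cached <- read.csv("results/data_planted/features.csv")
stopifnot(max(abs(as.matrix(feats[-1]) - as.matrix(cached[-1]))) < 1e-8)
message("re-extracted features agree with the generation-time cache")

rng <- t(apply(feats[-1], 2, range))
message("feature value ranges (first 6 shown):")
print(round(utils::head(rng), 3))
message("wrote results/features.csv")
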
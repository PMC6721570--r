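#!/usr/bin/env Rscript
# Stage 3: univariate survival screening.
#
# Each of the 45 radiomic features is dichotomized at its cohort median;
# the two groups are compared by log-rank test and univariate Cox hazard
# ratio, and p-values are Holm-Bonferroni corrected across the family.
# The expression block is screened the same way at raw p < 0.05 to
# define the transcriptomic panel carried into the integrative models.

suppressPackageStartupMessages(library(radsurv))

clin <- read.csv("results/data_planted/clinical.csv")
feats <- read.csv("results/features.csv")
stopifnot(identical(clin$patient_id, feats$patient_id))

screen <- univariate_screen(feats[-1], clin$os_days, clin$event)
screen <- screen[order(screen$p_adjusted), ]
write.csv(screen, "results/screen.csv", row.names = FALSE)

sig <- subset(screen, p_adjusted < 0.05)
message(nrow(sig), " of 45 features significant after Holm correction:")
print(sig[, c("feature", "p_adjusted", "hr", "ci_low", "ci_high")],
      row.names = FALSE, digits = 3)

expr <- read.csv("results/data_planted/expression.csv")
tx <- transcriptome_screen(expr[match(clin$patient_id, expr$patient_id), ],
                           clin$os_days, clin$event)
writeLines(tx$selected, "results/transcriptome_panel.txt")
message(length(tx$selected), " of ", ncol(expr) - 1,
        " expression genes retained at raw p < 0.05 ",
        "(null expectation ~5%)")
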
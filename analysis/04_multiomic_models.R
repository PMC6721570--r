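#!/usr/bin/env Rscript
# Stage 4: multi-omic integrative models.
#
# Builds the median-OS outcome (censored times imputed by the
# conditional-mean rule), then fits 500-tree random forests over a
# ladder of feature-block combinations: radiomics alone, radiomics +
# genomics, radiomics + transcriptomic panel, radiomics + proteins, and
# the full integration with clinical variables (age, therapy type).
# Each model is scored by stratified 10-fold cross-validated AUC; the
# full model is additionally evaluated on a held-out 100/100 split with
# log-rank validation of the predicted short/long survival groups, and
# AUC differences between models are compared by chi-square on the
# correct/incorrect classification counts.

suppressPackageStartupMessages(library(radsurv))

clin <- read.csv("results/data_planted/clinical.csv")
feats <- read.csv("results/features.csv")
mut <- read.csv("results/data_planted/mutations.csv")
expr <- read.csv("results/data_planted/expression.csv")
prot <- read.csv("results/data_planted/proteins.csv")
panel <- readLines("results/transcriptome_panel.txt")

outcome <- make_outcome(clin$os_days, clin$event)
message("outcome: median imputed OS ", round(outcome$cutoff_days),
        " days; ", sum(outcome$labels), " long / ",
        sum(outcome$labels == 0), " short")

blocks <- list(
  radiomic = feats,
  clinical = clin[, c("patient_id", "age", "therapy_type")],
  genomic = mut,
  transcriptomic = if (length(panel)) expr[, c("patient_id", panel)],
  protein = prot)

combos <- list(
  radiomics       = "radiomic",
  radiomics_gen   = c("radiomic", "genomic"),
  radiomics_tx    = c("radiomic", "transcriptomic"),
  radiomics_prot  = c("radiomic", "protein"),
  integrated_all  = c("radiomic", "clinical", "genomic",
                      "transcriptomic", "protein"))

cv <- list()
for (nm in names(combos)) {
  tab <- integrate_blocks(blocks[combos[[nm]]])
  tab <- tab[match(clin$patient_id, rownames(tab)), ]
  fit <- crossval_auc(tab, outcome$labels, n_trees = 500, k = 10,
                      seed = 11)
  cv[[nm]] <- list(blocks = combos[[nm]], mean_auc = fit$mean_auc,
                   pooled_auc = fit$pooled_auc,
                   fold_aucs = fit$fold_aucs,
                   predicted = fit$predicted_groups)
  message(sprintf("%-15s mean 10-fold AUC = %.3f", nm, fit$mean_auc))
}

# chi-square comparison: radiomics-only vs full integration, on the
# correct/incorrect out-of-fold classification counts
correct <- function(m) m$predicted == outcome$labels
tab22 <- rbind(table(factor(correct(cv$radiomics), c(FALSE, TRUE))),
               table(factor(correct(cv$integrated_all), c(FALSE, TRUE))))
cmp <- chi_square_2x2(tab22)
message(sprintf("radiomics vs integrated chi-square = %.2f (p = %.3g)",
                cmp$statistic, cmp$p_value))

# hold-out 100/100 evaluation of the full integration
tab_all <- integrate_blocks(blocks[combos$integrated_all])
tab_all <- tab_all[match(clin$patient_id, rownames(tab_all)), ]
ho <- train_test_eval(tab_all, outcome$labels, clin$os_days, clin$event,
                      split = c(100, 100), n_trees = 500, seed = 202)
message(sprintf(
  "hold-out test AUC = %.3f; log-rank p = %.3g; HR = %.2f (%.2f-%.2f)",
  ho$auc, ho$logrank$p_value, ho$hr$hr, ho$hr$ci_low, ho$hr$ci_high))

imp <- sort(crossval_auc(tab_all, outcome$labels, n_trees = 300, k = 10,
                         seed = 77)$importances, decreasing = TRUE)
message("top 5 permutation importances: ",
        paste(names(imp)[1:5], collapse = ", "))
write.csv(data.frame(feature = names(imp), importance = unname(imp)),
          "results/importances.csv", row.names = FALSE)

jsonlite::write_json(
  list(cv = lapply(cv, function(m) m[c("blocks", "mean_auc",
                                       "pooled_auc", "fold_aucs")]),
       model_comparison = cmp,
       holdout = list(auc = ho$auc, logrank_p = ho$logrank$p_value,
                      hr = ho$hr$hr, ci = c(ho$hr$ci_low, ho$hr$ci_high)),
       outcome_cutoff_days = outcome$cutoff_days),
  "results/models.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("wrote results/models.json and results/importances.csv")
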
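#' Cohort demographics summary table
#'
#' Counts and cohort percentages per stratum, in the layout of a
#' standard clinical Table 1: age (<=65 / >65), sex, KPS (<70 / >=70 /
#' Unknown), optional MGMT methylation / IDH1 / surgery columns (strata
#' emitted verbatim, including "NA" strata), radiation and chemotherapy
#' flags derived from `therapy_type` when explicit columns are absent,
#' and survival bands (<1 year, 1-4 years, >4 years) with censored
#' counts. Percentages are reported to two decimals, truncated toward
#' zero (not rounded).
#'
#' @param clinical data.frame with columns `patient_id`, `age`, `sex`,
#'   `kps`, `therapy_type`, `os_days`, `event`; optional columns
#'   `mgmt_methylation`, `idh1`, `surgery`, `radiation`, `chemotherapy`.
#' @return data.frame with columns `variable`, `stratum`, `count`,
#'   `percent`, `censored`.
#' @export
cohort_summary <- function(clinical) {
  need <- c("patient_id", "age", "sex", "kps", "therapy_type",
            "os_days", "event")
  miss <- setdiff(need, names(clinical))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  n <- nrow(clinical)
  pct <- function(k) trunc(k / n * 10000) / 100
  row <- function(var, strat, k, cens = NA_integer_)
    data.frame(variable = var, stratum = strat, count = k,
               percent = pct(k), censored = cens)
  verbatim <- function(var, v) {
    v <- ifelse(is.na(v), "NA", as.character(v))
    do.call(rbind, lapply(unique(v), function(s)
      row(var, s, sum(v == s))))
  }

  out <- list(
    row("Age", "<=65", sum(clinical$age <= 65)),
    row("Age", ">65", sum(clinical$age > 65)),
    verbatim("Sex", clinical$sex),
    row("KPS", "<70", sum(!is.na(clinical$kps) & clinical$kps < 70)),
    row("KPS", ">=70", sum(!is.na(clinical$kps) & clinical$kps >= 70)),
    row("KPS", "Unknown", sum(is.na(clinical$kps))))

  for (optional in c("mgmt_methylation", "idh1", "surgery"))
    if (optional %in% names(clinical))
      out <- c(out, list(verbatim(optional, clinical[[optional]])))

  rad <- if ("radiation" %in% names(clinical)) clinical$radiation
         else ifelse(is.na(clinical$therapy_type), NA,
                     ifelse(clinical$therapy_type %in% c("RT+TMZ", "RT"),
                            "Yes", "No"))
  chem <- if ("chemotherapy" %in% names(clinical)) clinical$chemotherapy
          else ifelse(is.na(clinical$therapy_type), NA,
                      ifelse(clinical$therapy_type == "RT+TMZ",
                             "Yes", "No"))
  out <- c(out, list(verbatim("Radiation treatment", rad),
                     verbatim("Chemotherapy", chem)))

  yrs <- clinical$os_days / 365.25
  band <- cut(yrs, c(-Inf, 1, 4, Inf), labels = c("<1 year", "1-4 years",
                                                  ">4 years"))
  out <- c(out, list(do.call(rbind, lapply(levels(band), function(b)
    row("Survival", b, sum(band == b),
        cens = sum(band == b & clinical$event == 0))))))

  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Configuration of an end-to-end pipeline run
#'
#' Exactly one data source must be given: a synthetic `cohort_config`,
#' or a directory in the on-disk layout written by [generate_cohort()]
#' (NIfTI volumes/masks plus clinical/mutations/expression/proteins
#' CSV tables).
#'
#' @param cohort optional `cohort_config` for a synthetic source.
#' @param data_dir optional path to an existing dataset directory.
#' @param blocks feature blocks to integrate, a subset of
#'   `c("radiomic", "clinical", "genomic", "transcriptomic", "protein")`.
#' @param mode analysis mode: `"cv"` (10-fold cross-validation),
#'   `"holdout"` (train/test split) or `"uncensored"` (cross-validation
#'   on uncensored patients only, no imputation).
#' @param split train/test sizes or fractions for holdout mode.
#' @param n_trees,n_folds random-forest size and CV folds.
#' @param model_seed seed for fold assignment / splitting and forests.
#' @param out_dir output directory for the report bundle.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = NULL, data_dir = NULL,
                            blocks = c("radiomic", "clinical", "genomic",
                                       "transcriptomic", "protein"),
                            mode = c("cv", "holdout", "uncensored"),
                            split = c(0.5, 0.5), n_trees = 500L,
                            n_folds = 10L, model_seed = 1L,
                            out_dir = tempfile("radsurv_run_")) {
  if (is.null(cohort) == is.null(data_dir))
    stop("exactly one data source: give either `cohort` or `data_dir`")
  if (!is.null(cohort)) stopifnot(inherits(cohort, "cohort_config"))
  blocks <- match.arg(blocks, c("radiomic", "clinical", "genomic",
                                "transcriptomic", "protein"),
                      several.ok = TRUE)
  structure(list(cohort = cohort, data_dir = data_dir, blocks = blocks,
                 mode = match.arg(mode), split = split,
                 n_trees = as.integer(n_trees),
                 n_folds = as.integer(n_folds),
                 model_seed = as.integer(model_seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full pipeline and write a report bundle
#'
#' Executes, in order: data acquisition (synthetic generation or loading
#' from disk), volume preprocessing and 45-feature radiomic extraction,
#' univariate median-split survival screening with Holm correction,
#' transcriptome screening, multi-omic block integration, censored-time
#' imputation and median-OS labelling, random-forest modelling (CV or
#' hold-out), and survival validation of the predicted groups. Every
#' stage logs its input/output counts to stderr; all numeric results
#' land in `report.json` (plus CSV tables) under the configured output
#' directory. Reruns with the same configuration produce byte-identical
#' JSON.
#'
#' @param config a `pipeline_config`.
#' @return the report list, invisibly; written to
#'   `file.path(config$out_dir, "report.json")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- function(...) message("[radsurv] ", ...)

  # --- stage 1: data ---------------------------------------------------
  if (!is.null(config$cohort)) {
    data_dir <- file.path(config$out_dir, "data")
    log("generating synthetic cohort: n = ", config$cohort$n_patients)
    generate_cohort(config$cohort, out_dir = data_dir)
  } else {
    data_dir <- config$data_dir
  }
  rd <- function(f) {
    p <- file.path(data_dir, f)
    if (!file.exists(p)) stop("stage data: missing ", p)
    utils::read.csv(p, check.names = FALSE)
  }
  clinical <- rd("clinical.csv")
  mutations <- rd("mutations.csv")
  expr <- rd("expression.csv")
  proteins <- rd("proteins.csv")
  n0 <- nrow(clinical)
  log("loaded clinical table: ", n0, " patients")

  # --- stage 2: preprocess + extract -----------------------------------
  vol_paths <- file.path(data_dir,
                         sprintf("vol_%s.nii.gz", clinical$patient_id))
  mask_paths <- file.path(data_dir,
                          sprintf("mask_%s.nii.gz", clinical$patient_id))
  have <- file.exists(vol_paths) & file.exists(mask_paths)
  if (!all(have))
    log(sum(!have), " patient(s) dropped: missing volume or mask file")
  feats <- extract_cohort_features(vol_paths[have], mask_paths[have],
                                   patient_ids = clinical$patient_id[have])
  log("extracted radiomic features: ", nrow(feats), " patients x ",
      ncol(feats) - 1L, " features")
  keep <- clinical$patient_id %in% feats$patient_id
  clinical <- clinical[keep, ]
  dropped <- n0 - nrow(clinical)

  # --- stage 3: univariate screen --------------------------------------
  screen <- univariate_screen(
    feats[match(clinical$patient_id, feats$patient_id), -1],
    clinical$os_days, clinical$event)
  log("univariate screen: ",
      sum(screen$p_adjusted < 0.05, na.rm = TRUE),
      " features significant after Holm correction")

  # --- stage 4: transcriptome screen -----------------------------------
  tx_sel <- character(0)
  if ("transcriptomic" %in% config$blocks) {
    ord <- match(clinical$patient_id, expr$patient_id)
    ts <- transcriptome_screen(expr[ord, ], clinical$os_days,
                               clinical$event)
    tx_sel <- ts$selected
    log("transcriptome screen: ", length(tx_sel), " of ",
        ncol(expr) - 1L, " genes retained (raw p < 0.05)")
  }

  # --- stage 5: integrate ----------------------------------------------
  blocks <- list(
    radiomic = feats,
    clinical = clinical[, c("patient_id", "age", "therapy_type")],
    genomic = mutations,
    transcriptomic = if (length(tx_sel))
      expr[, c("patient_id", tx_sel)] else NULL,
    protein = proteins)
  use <- intersect(config$blocks, names(blocks)[!vapply(blocks, is.null,
                                                        logical(1))])
  table <- integrate_blocks(blocks[use], include = use)
  table <- table[match(clinical$patient_id, rownames(table)), ]
  log("integrated blocks [", paste(use, collapse = ", "), "]: ",
      ncol(table), " feature columns")

  # --- stage 6: outcome ------------------------------------------------
  if (config$mode == "uncensored") {
    keep_u <- clinical$event == 1L
    log("uncensored-only mode: ", sum(!keep_u), " censored patients dropped")
    clinical <- clinical[keep_u, ]
    table <- table[keep_u, ]
    outcome <- list(labels = median_split(clinical$os_days),
                    cutoff_days = stats::median(clinical$os_days),
                    imputed = clinical$os_days)
  } else {
    outcome <- make_outcome(clinical$os_days, clinical$event)
  }
  log("outcome labels: cutoff ", round(outcome$cutoff_days, 1),
      " days; ", sum(outcome$labels), " long-term / ",
      sum(outcome$labels == 0), " short-term")

  # --- stage 7: model --------------------------------------------------
  if (config$mode == "holdout") {
    fit <- train_test_eval(table, outcome$labels, clinical$os_days,
                           clinical$event, split = config$split,
                           n_trees = config$n_trees,
                           seed = config$model_seed)
    model_report <- list(mode = "holdout", auc = fit$auc,
                         n_train = nrow(table) - length(fit$test_idx),
                         n_test = length(fit$test_idx))
    pred <- fit$predicted_groups
    val_time <- clinical$os_days[fit$test_idx]
    val_event <- clinical$event[fit$test_idx]
    importances <- fit$importances
  } else {
    fit <- crossval_auc(table, outcome$labels, n_trees = config$n_trees,
                        k = config$n_folds, seed = config$model_seed)
    model_report <- list(mode = config$mode, fold_aucs = fit$fold_aucs,
                         mean_auc = fit$mean_auc,
                         pooled_auc = fit$pooled_auc)
    pred <- fit$predicted_groups
    val_time <- clinical$os_days
    val_event <- clinical$event
    importances <- fit$importances
  }
  log("model AUC: ",
      round(if (config$mode == "holdout") fit$auc else fit$mean_auc, 4))

  # --- stage 8: survival validation of predicted groups ----------------
  validation <- NULL
  if (length(unique(pred)) == 2L && sum(val_event) > 0) {
    lr <- logrank_test(val_time, val_event, pred)
    hr <- hazard_ratio(val_time, val_event, pred)
    validation <- list(logrank_p = lr$p_value,
                       logrank_statistic = lr$statistic,
                       hr = hr$hr, ci_low = hr$ci_low, ci_high = hr$ci_high)
    km <- lapply(split(seq_along(pred), pred), function(ix)
      kaplan_meier(val_time[ix], val_event[ix]))
    km_df <- do.call(rbind, lapply(names(km), function(g)
      data.frame(group = g, time = km[[g]]$time, surv = km[[g]]$surv)))
    utils::write.csv(km_df,
                     file.path(config$out_dir, "km_predicted_groups.csv"),
                     row.names = FALSE)
  }

  imp_ord <- sort(importances, decreasing = TRUE)
  report <- list(
    config_hash = rlang::hash(unclass(config)),
    seeds = list(model = config$model_seed,
                 cohort = if (!is.null(config$cohort))
                   config$cohort$seed else NULL),
    feature_roster_version = "radsurv-45-v1",
    n_patients = nrow(clinical), n_dropped = dropped,
    blocks = use, n_feature_columns = ncol(table),
    outcome_cutoff_days = outcome$cutoff_days,
    demographics = cohort_summary(clinical),
    screen_significant =
      screen$feature[!is.na(screen$p_adjusted) & screen$p_adjusted < 0.05],
    model = model_report,
    validation = validation,
    top_importances = as.list(head(imp_ord, 10)))

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(screen, file.path(config$out_dir, "screen.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(feature = names(importances),
                              importance = unname(importances)),
                   file.path(config$out_dir, "importances.csv"),
                   row.names = FALSE)
  log("report bundle written to ", config$out_dir)
  invisible(report)
}
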
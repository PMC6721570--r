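#' Impute censored survival times
#'
#' Censored patients are known only to have survived past their last
#' follow-up. Each censored time is replaced by the mean survival of
#' uncensored patients whose time-to-death is greater than or equal to
#' the censored patient's last-visit time; a censored time exceeding
#' every uncensored time is kept as-is (the rule is otherwise undefined
#' there). Uncensored times are never altered, and imputation never
#' decreases a time.
#'
#' @param time survival times in days.
#' @param event event indicator (1 = death, 0 = censored).
#' @return numeric vector of imputed times.
#' @export
impute_censored <- function(time, event) {
  if (sum(event) == 0L)
    stop("all records censored: imputation undefined")
  dead <- time[event == 1L]
  out <- time
  for (k in which(event == 0L)) {
    pool <- dead[dead >= time[k]]
    if (length(pool)) out[k] <- mean(pool)
  }
  out
}

#' Median-OS outcome labels for classification
#'
#' Applies the censoring imputation then dichotomizes at the median of
#' the imputed overall survival: label 1 = long-term (>= median),
#' label 0 = short-term. The median cut-off gives (near) balanced
#' classes by construction.
#'
#' @param time,event survival records.
#' @return list with integer `labels`, `cutoff_days` (the median imputed
#'   OS) and the `imputed` times.
#' @export
make_outcome <- function(time, event) {
  imp <- impute_censored(time, event)
  labels <- median_split(imp)
  if (length(unique(labels)) != 2L)
    stop("degenerate outcome: a single survival class")
  list(labels = labels, cutoff_days = stats::median(imp), imputed = imp)
}

# AUC of predicted class-1 probability against binary labels
roc_auc <- function(labels, scores) {
  as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c(0, 1),
                                 direction = "<", quiet = TRUE)))
}

# seeded stratified fold assignment: shuffle within class, deal
# round-robin so every fold holds both classes
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Cross-validated random-forest survival-group classifier
#'
#' Stratified 10-fold cross-validation of a 500-tree random forest
#' predicting short- vs long-term survival. Per fold the forest is
#' trained on nine folds and scores the held-out fold; the AUC of the
#' held-out class-1 probabilities is recorded per fold and averaged (the
#' headline metric), with the pooled out-of-fold AUC reported alongside.
#' Feature importances are sd-normalized out-of-bag permutation
#' importances (mean decrease in accuracy scaled by its standard error
#' across trees), averaged over the folds. Deterministic given `seed`.
#'
#' @param table feature data.frame/matrix (numeric columns only).
#' @param labels binary outcome labels (0/1).
#' @param n_trees trees per forest (default 500).
#' @param k number of folds (default 10).
#' @param seed integer RNG seed.
#' @return a `model_result`: list with `fold_aucs`, `mean_auc`,
#'   `pooled_auc`, `out_of_fold_scores`, `predicted_groups` (score >=
#'   0.5), `importances`, `seed`.
#' @export
crossval_auc <- function(table, labels, n_trees = 500L, k = 10L,
                         seed = 1L) {
  x <- as.data.frame(table)
  stopifnot(nrow(x) == length(labels))
  if (min(table(labels)) < k)
    stop("need at least k patients per class for stratified ", k, "-fold CV")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- stratified_folds(labels, k)
  y <- factor(labels, levels = c(0, 1))
  scores <- rep(NA_real_, length(labels))
  fold_aucs <- numeric(k)
  imp <- matrix(0, ncol(x), k,
                dimnames = list(colnames(x), NULL))
  for (f in seq_len(k)) {
    tr <- fold != f
    fit <- randomForest::randomForest(x[tr, , drop = FALSE], y[tr],
                                      ntree = n_trees, importance = TRUE)
    pr <- stats::predict(fit, x[!tr, , drop = FALSE], type = "prob")[, "1"]
    scores[!tr] <- pr
    fold_aucs[f] <- roc_auc(labels[!tr], pr)
    imp[, f] <- randomForest::importance(fit, type = 1, scale = TRUE)[, 1]
  }
  structure(list(fold_aucs = fold_aucs, mean_auc = mean(fold_aucs),
                 pooled_auc = roc_auc(labels, scores),
                 out_of_fold_scores = scores,
                 predicted_groups = as.integer(scores >= 0.5),
                 importances = rowMeans(imp), seed = seed),
            class = "model_result")
}

#' Permutation importance of features for the survival classifier
#'
#' The sd-normalized out-of-bag permutation importances of
#' [crossval_auc()] (per tree: increase in OOB error after permuting a
#' feature; averaged over trees, divided by the standard deviation of
#' the tree-level increases, then averaged across the CV folds).
#' Positive values mark predictive features; values near zero or
#' negative mark non-predictive ones.
#'
#' @inheritParams crossval_auc
#' @return named numeric vector of importances, one per feature column.
#' @export
permutation_importance <- function(table, labels, n_trees = 500L,
                                   k = 10L, seed = 1L) {
  crossval_auc(table, labels, n_trees = n_trees, k = k, seed = seed)$importances
}

#' Hold-out train/test evaluation with survival validation
#'
#' Randomly assigns patients to disjoint training and testing partitions
#' (100/100 by default), fits a 500-tree random forest on the training
#' partition only, and evaluates on the held-out partition: AUC of the
#' predicted class-1 probability, predicted short/long groups
#' (probability >= 0.5), and — when survival records are supplied — the
#' Kaplan-Meier curves, log-rank test and hazard ratio between the
#' predicted groups on the test set.
#'
#' @param table feature data.frame (numeric columns).
#' @param labels binary outcome labels.
#' @param time,event optional survival records for validating predicted
#'   groups.
#' @param split integer pair (n_train, n_test) or fractions summing to
#'   at most 1.
#' @param n_trees trees (default 500).
#' @param seed integer RNG seed.
#' @return list with `auc`, `test_idx`, `scores`, `predicted_groups`,
#'   `importances`, and (with survival input) `logrank` and `hr`.
#' @export
train_test_eval <- function(table, labels, time = NULL, event = NULL,
                            split = c(100L, 100L), n_trees = 500L,
                            seed = 1L) {
  x <- as.data.frame(table)
  n <- nrow(x)
  if (all(split <= 1)) split <- round(split * n)
  split <- as.integer(split)
  if (sum(split) > n)
    stop("partition sizes ", paste(split, collapse = "+"),
         " exceed cohort size ", n)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  perm <- sample(n)
  tr_idx <- perm[seq_len(split[1])]
  te_idx <- perm[split[1] + seq_len(split[2])]
  if (length(unique(labels[tr_idx])) < 2L ||
      length(unique(labels[te_idx])) < 2L)
    stop("a partition contains a single class; use a different seed")
  y <- factor(labels, levels = c(0, 1))
  fit <- randomForest::randomForest(x[tr_idx, , drop = FALSE], y[tr_idx],
                                    ntree = n_trees, importance = TRUE)
  pr <- stats::predict(fit, x[te_idx, , drop = FALSE], type = "prob")[, "1"]
  out <- list(auc = roc_auc(labels[te_idx], pr), test_idx = te_idx,
              scores = pr, predicted_groups = as.integer(pr >= 0.5),
              importances =
                randomForest::importance(fit, type = 1, scale = TRUE)[, 1],
              seed = seed)
  if (!is.null(time) && length(unique(out$predicted_groups)) == 2L) {
    out$logrank <- logrank_test(time[te_idx], event[te_idx],
                                out$predicted_groups)
    out$hr <- hazard_ratio(time[te_idx], event[te_idx],
                           out$predicted_groups)
  }
  out
}

#' Assemble a multi-omic feature table from named blocks
#'
#' Column-wise concatenation of the requested blocks over the patients
#' shared by all of them. Each block is a data.frame whose first column
#' is `patient_id`. Clinical categorical variables (sex, therapy type)
#' are one-hot encoded as indicator columns; every output column carries
#' a block tag in `attr(, "block")`. Patients missing from any requested
#' block are dropped with a message.
#'
#' @param blocks named list of data.frames (names become block tags,
#'   e.g. radiomic, clinical, genomic, transcriptomic, protein).
#' @param include character vector of block names to include (default
#'   all).
#' @return data.frame of features with `patient_id` rownames and a
#'   `block` attribute (character vector parallel to the columns).
#' @export
integrate_blocks <- function(blocks, include = names(blocks)) {
  stopifnot(length(include) >= 1, all(include %in% names(blocks)))
  blocks <- blocks[include]
  ids <- Reduce(intersect, lapply(blocks, function(b) b$patient_id))
  if (!length(ids)) stop("no patient shared by all requested blocks")
  n_all <- length(unique(unlist(lapply(blocks, `[[`, "patient_id"))))
  if (n_all > length(ids))
    message(n_all - length(ids),
            " patient(s) dropped: missing in at least one block")
  cols <- list()
  tags <- character(0)
  for (bn in names(blocks)) {
    b <- blocks[[bn]]
    b <- b[match(ids, b$patient_id), setdiff(names(b), "patient_id"),
           drop = FALSE]
    enc <- list()
    for (cn in names(b)) {
      v <- b[[cn]]
      if (is.character(v) || is.factor(v)) {
        v <- factor(v)
        for (lv in levels(v))
          enc[[paste0(cn, "_", make.names(tolower(lv)))]] <-
            as.integer(v == lv)
      } else {
        enc[[cn]] <- as.numeric(v)
      }
    }
    enc <- as.data.frame(enc)
    cols[[bn]] <- enc
    tags <- c(tags, rep(bn, ncol(enc)))
  }
  out <- do.call(cbind, unname(cols))
  if (anyDuplicated(names(out)))
    stop("duplicate column names across blocks")
  rownames(out) <- ids
  attr(out, "block") <- tags
  out
}

#' Univariate transcriptome survival screen
#'
#' Per-gene median-split log-rank screen of an expression matrix:
#' genes whose raw (pre-correction) log-rank p-value falls below the
#' threshold are retained as the transcriptomic block for integration.
#'
#' @param expression data.frame with `patient_id` plus one column per
#'   gene, or a numeric matrix.
#' @param time,event survival records aligned with the rows.
#' @param p_threshold raw p-value cut-off (default 0.05).
#' @return list with `selected` gene names and the per-gene `p_values`.
#' @export
transcriptome_screen <- function(expression, time, event,
                                 p_threshold = 0.05) {
  x <- as.data.frame(expression)
  x <- x[, setdiff(names(x), "patient_id"), drop = FALSE]
  pv <- vapply(x, function(g) {
    tryCatch(logrank_test(time, event, median_split(g))$p_value,
             error = function(e) NA_real_)
  }, numeric(1))
  list(selected = names(pv)[!is.na(pv) & pv < p_threshold],
       p_values = pv)
}
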
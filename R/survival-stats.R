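#' Kaplan-Meier product-limit survival curve
#'
#' Wraps [survival::survfit()] into a plain summary: distinct event
#' times, survival probabilities, at-risk and event counts, and the
#' median survival (first time at which S(t) <= 0.5, `NA` if the curve
#' never reaches 0.5).
#'
#' @param time positive survival times in days.
#' @param event event indicator: 1 = death observed, 0 = censored.
#' @return a `survival_curve`: list with `time`, `surv`, `n_risk`,
#'   `n_event`, `median_survival`.
#' @export
kaplan_meier <- function(time, event) {
  if (!length(time)) stop("no survival records")
  if (any(!is.finite(time)) || any(time <= 0))
    stop("survival times must be finite and positive")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1]]
         else NA_real_
  structure(list(time = fit$time[keep], surv = fit$surv[keep],
                 n_risk = fit$n.risk[keep], n_event = fit$n.event[keep],
                 median_survival = med),
            class = "survival_curve")
}

#' Two-group log-rank test
#'
#' Standard one-degree-of-freedom log-rank chi-square from the observed
#' and expected event counts at each distinct event time, via
#' [survival::survdiff()]; two-sided p-value.
#'
#' @param time,event survival records.
#' @param group binary group labels (two distinct values).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
logrank_test <- function(time, event, group) {
  if (length(unique(group)) != 2L)
    stop("log-rank test needs exactly two groups")
  if (sum(event) == 0L)
    stop("log-rank test undefined without any observed event")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  stat <- sd$chisq
  list(statistic = stat,
       p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L)
}

#' Hazard ratio between two groups (univariate Cox model)
#'
#' HR = exp(beta) from a single-covariate Cox proportional-hazards
#' partial likelihood (Breslow tie handling, Newton-type maximization via
#' [survival::coxph()]) comparing `group == levels[2]` against the first
#' level; 95% Wald confidence interval exp(beta +/- 1.96 se). Complete
#' separation (monotone likelihood) is flagged with infinite CI bounds.
#'
#' @param time,event survival records.
#' @param group binary group labels.
#' @return list with `hr`, `ci_low`, `ci_high`, `beta`, `se`, `p_value`,
#'   `flagged` (TRUE when the fit is degenerate).
#' @export
hazard_ratio <- function(time, event, group) {
  if (length(unique(group)) != 2L)
    stop("hazard ratio needs exactly two groups")
  if (sum(event) == 0L) stop("no observed events")
  g <- as.integer(factor(group)) - 1L
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ g, ties = "breslow"),
    warning = function(w) invokeRestart("muffleWarning"))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  flagged <- !is.finite(beta) || !is.finite(se) || abs(beta) > 15
  hr <- exp(beta)
  ci <- exp(beta + c(-1, 1) * 1.96 * se)
  if (flagged) ci <- c(if (beta > 0) hr / Inf else 0, Inf)
  list(hr = hr, ci_low = ci[1], ci_high = ci[2], beta = beta, se = se,
       p_value = stats::pchisq((beta / se)^2, 1, lower.tail = FALSE),
       flagged = flagged)
}

#' Median-split group labels
#'
#' Dichotomizes a numeric vector at its sample median (standard even/odd
#' convention); label 1 means value >= median, so ties at the median go
#' to the high group. All-identical input is a degenerate split and an
#' error.
#'
#' @param values numeric vector, length >= 2.
#' @return integer vector of 0/1 labels.
#' @export
median_split <- function(values) {
  if (length(values) < 2L) stop("need at least two values")
  if (length(unique(values)) == 1L)
    stop("degenerate split: all values identical")
  as.integer(values >= stats::median(values))
}

#' Holm-Bonferroni step-down adjustment
#'
#' Family-wise error-rate control: sorted ascending, p(k) is multiplied
#' by (m - k + 1), monotonicity enforced by running maximum, capped at 1,
#' returned in input order (delegates to [stats::p.adjust()]).
#'
#' @param pvals p-values in `[0, 1]`.
#' @return adjusted p-values, same order.
#' @export
holm_bonferroni <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "holm")
}

#' Wilcoxon rank-sum test with midrank ties
#'
#' For combined sample size up to 10 the two-sided p-value is exact, by
#' enumeration of all group assignments of the (mid)ranks; above that a
#' normal approximation with tie-corrected variance and no continuity
#' correction is used. Degenerate all-tied input returns p = 1.
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (rank sum of `x`), `p_value`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be nonempty")
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  ew <- nx * (n + 1) / 2
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = w, p_value = 1, method = "degenerate"))
  if (n <= 10L) {
    sums <- utils::combn(r, nx, sum)
    p <- mean(abs(sums - ew) >= abs(w - ew) - 1e-12)
    return(list(statistic = w, p_value = p, method = "exact"))
  }
  ties <- table(r)
  varw <- nx * (n - nx) / 12 *
    ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (w - ew) / sqrt(varw)
  list(statistic = w, p_value = 2 * stats::pnorm(-abs(z)),
       method = "normal")
}

#' Kruskal-Wallis rank test across k groups
#'
#' Rank-based one-way comparison with midrank tie correction
#' ([stats::kruskal.test()]); all-tied input returns H = 0, p = 1.
#'
#' @param groups list of numeric vectors, each nonempty.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (any(!lengths(groups))) stop("every group must be nonempty")
  vals <- unlist(groups)
  if (length(unique(vals)) == 1L)
    return(list(statistic = 0, p_value = 1, df = length(groups) - 1L))
  kt <- stats::kruskal.test(vals, factor(rep(seq_along(groups),
                                             lengths(groups))))
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       df = unname(kt$parameter))
}

#' Pearson chi-square test on a 2x2 table
#'
#' No continuity correction, one degree of freedom. Zero row or column
#' margins are an error.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2L)) stop("table must be 2x2")
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin: chi-square undefined")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, df = 1L)
}

#' Univariate median-split survival screen
#'
#' The feature-screening step: each feature is dichotomized at its
#' median, the two groups are compared by log-rank test and a univariate
#' Cox hazard ratio, and the log-rank p-values are Holm-Bonferroni
#' adjusted across the feature family. Degenerate features (all-tied,
#' no split) are retained as flagged rows with NA statistics and do not
#' enter the correction family.
#'
#' @param features data.frame or matrix of feature columns (rows =
#'   patients, complete).
#' @param time,event survival records aligned with the rows.
#' @return data.frame with one row per feature: `feature`, `statistic`,
#'   `p_value`, `p_adjusted`, `hr`, `ci_low`, `ci_high`, `flagged`.
#' @export
univariate_screen <- function(features, time, event) {
  features <- as.data.frame(features)
  if (nrow(features) != length(time))
    stop("features and survival records differ in length")
  rows <- lapply(names(features), function(f) {
    res <- tryCatch({
      grp <- median_split(features[[f]])
      lr <- logrank_test(time, event, grp)
      hr <- hazard_ratio(time, event, grp)
      data.frame(feature = f, statistic = lr$statistic,
                 p_value = lr$p_value, hr = hr$hr, ci_low = hr$ci_low,
                 ci_high = hr$ci_high, flagged = hr$flagged)
    }, error = function(e)
      data.frame(feature = f, statistic = NA_real_, p_value = NA_real_,
                 hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 flagged = TRUE))
    res
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- NA_real_
  ok <- !is.na(out$p_value)
  out$p_adjusted[ok] <- holm_bonferroni(out$p_value[ok])
  out[, c("feature", "statistic", "p_value", "p_adjusted",
          "hr", "ci_low", "ci_high", "flagged")]
}
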
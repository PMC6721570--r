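#' Draw proportional-hazards survival times with planted effects
#'
#' Event times are exponential with per-patient hazard
#' `baseline * exp(sum(beta_f * z_f))`, where the `z_f` are standardized
#' feature columns named by `effects`. Censoring is independent of the
#' covariates: an exponential censoring time whose rate is solved
#' numerically so the expected censored fraction matches
#' `censoring_rate`. The observed record is `min(event, censor)` with an
#' event flag.
#'
#' @param features numeric matrix or data.frame of standardized feature
#'   columns (rows = patients); may be NULL when `effects` is empty.
#' @param effects named numeric vector mapping feature name to log-hazard
#'   coefficient; empty vector means no covariate effect.
#' @param baseline baseline hazard rate per day.
#' @param censoring_rate target censored fraction in `[0, 1)`.
#' @param seed integer RNG seed.
#' @return data.frame with columns `os_days` (> 0) and `event` (1 =
#'   death observed, 0 = censored).
#' @export
generate_survival <- function(features, effects = numeric(0),
                              baseline = 1 / 400, censoring_rate = 0.2,
                              seed = 1L) {
  if (baseline <= 0) stop("baseline hazard must be positive")
  if (censoring_rate < 0 || censoring_rate >= 1)
    stop("censoring_rate must be in [0, 1)")
  if (length(effects)) {
    if (is.null(names(effects)) || any(!nzchar(names(effects))))
      stop("effects must be a named vector")
    missing_f <- setdiff(names(effects), colnames(features))
    if (length(missing_f))
      stop("planted effect on unknown feature(s): ",
           paste(missing_f, collapse = ", "))
    lp <- as.matrix(features[, names(effects), drop = FALSE]) %*% effects
    hazard <- baseline * exp(as.numeric(lp))
    n <- nrow(features)
  } else {
    n <- if (is.null(features)) 1L else nrow(features)
    hazard <- rep(baseline, n)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  t_event <- stats::rexp(n, rate = hazard)

  if (censoring_rate > 0) {
    crate <- solve_censoring_rate(hazard, censoring_rate)
    t_cens <- stats::rexp(n, rate = crate)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(1L, n)
    time <- t_event
  }
  data.frame(os_days = pmax(time, .Machine$double.eps), event = event)
}

# with T ~ exp(h_i) and independent C ~ exp(c), P(censored | i) =
# c / (c + h_i); solve mean_i c / (c + h_i) = target for c
solve_censoring_rate <- function(hazard, target) {
  f <- function(lc) mean(exp(lc) / (exp(lc) + hazard)) - target
  lo <- log(min(hazard)) - 20
  hi <- log(max(hazard)) + 20
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root |> exp()
}
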
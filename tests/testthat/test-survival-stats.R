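test_that("Kaplan-Meier product-limit matches hand computation", {
  # all events: S = 2/3, 1/3, 0
  km <- kaplan_meier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # censoring at 2: S(1) = 2/3, S(3) = 0 (risk set of 1 at t = 3)
  km2 <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$time, c(1, 3))
  expect_equal(km2$surv, c(2 / 3, 0))
  # no censoring: equals the empirical survival function
  set.seed(2)
  tt <- sample(1:50, 20)
  km3 <- kaplan_meier(tt, rep(1, 20))
  expect_equal(km3$surv, 1 - sapply(km3$time, function(u) mean(tt <= u)))
  # probabilities always non-increasing, median is first S <= 0.5
  expect_true(all(diff(km3$surv) <= 0))
  expect_equal(km3$median_survival, km3$time[which(km3$surv <= 0.5)[1]])
  expect_error(kaplan_meier(numeric(0), numeric(0)), "no survival")
})

test_that("log-rank test is symmetric and matches the textbook oracle", {
  tA <- c(1, 2, 3); tB <- c(4, 5, 6)
  r <- logrank_test(c(tA, tB), rep(1, 6), rep(0:1, each = 3))
  oracle <- naive_logrank(c(tA, tB), rep(1, 6), rep(0:1, each = 3))
  expect_equal(r$statistic, oracle$statistic, tolerance = 1e-10)
  expect_equal(r$p_value, oracle$p_value, tolerance = 1e-10)

  # swapping labels changes nothing
  r2 <- logrank_test(c(tA, tB), rep(1, 6), rep(1:0, each = 3))
  expect_equal(r$statistic, r2$statistic, tolerance = 1e-12)

  # identical groups: statistic 0, p = 1
  r3 <- logrank_test(rep(c(1, 2, 3), 2), rep(1, 6), rep(0:1, each = 3))
  expect_equal(r3$statistic, 0, tolerance = 1e-12)
  expect_equal(r3$p_value, 1, tolerance = 1e-12)

  # censored random data still agrees with the oracle
  set.seed(8)
  tt <- stats::rexp(40, 1 / 100)
  ev <- stats::rbinom(40, 1, 0.7)
  gg <- stats::rbinom(40, 1, 0.5)
  r4 <- logrank_test(tt, ev, gg)
  o4 <- naive_logrank(tt, ev, gg)
  expect_equal(r4$statistic, o4$statistic, tolerance = 1e-10)

  expect_error(logrank_test(c(1, 2), c(0, 0), c(0, 1)), "event")
})

test_that("hazard ratio behaves under the null, inversion and recovery", {
  # null: identical event-time distributions, HR near 1
  set.seed(3)
  tt <- stats::rexp(500, 1 / 300)
  gg <- rep(0:1, 250)
  hr <- hazard_ratio(tt, rep(1, 500), gg)
  expect_gte(hr$hr, 0.8)
  expect_lte(hr$hr, 1.25)
  expect_true(hr$ci_low <= hr$hr && hr$hr <= hr$ci_high)

  # relabelling inverts the ratio
  hr2 <- hazard_ratio(tt, rep(1, 500), 1 - gg)
  expect_equal(hr$hr, 1 / hr2$hr, tolerance = 1e-8)

  # planted group effect beta = log 2 at n = 1000
  set.seed(4)
  g <- rep(0:1, 500)
  tt2 <- stats::rexp(1000, (1 / 400) * 2^g)
  hr3 <- hazard_ratio(tt2, rep(1, 1000), g)
  expect_gte(hr3$hr, 1.8)
  expect_lte(hr3$hr, 2.2)
})

test_that("hazard ratio recovers planted effects within 2 SE most of the time", {
  hits <- vapply(1:20, function(k) {
    set.seed(600 + k)
    g <- rep(0:1, 250)
    tt <- stats::rexp(500, (1 / 400) * exp(log(2) * g))
    hr <- hazard_ratio(tt, rep(1, 500), g)
    abs(hr$beta - log(2)) <= 2 * hr$se
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("median split uses the >= tie convention", {
  expect_equal(median_split(c(5, 10, 15, 20)), c(0L, 0L, 1L, 1L))
  expect_equal(median_split(c(1, 2, 2, 3)), c(0L, 1L, 1L, 1L))
  expect_error(median_split(rep(3, 5)), "degenerate")
  expect_error(median_split(1), "at least two")
  for (seed in 1:5) {
    set.seed(seed)
    lab <- median_split(stats::rnorm(21))
    expect_true(all(c(0L, 1L) %in% lab))
  }
})

test_that("Holm-Bonferroni adjustment is exact and well-ordered", {
  expect_equal(holm_bonferroni(c(0.01, 0.02, 0.04)), c(0.03, 0.04, 0.04))
  expect_equal(holm_bonferroni(0.5), 0.5)
  expect_equal(holm_bonferroni(rep(1, 4)), rep(1, 4))
  expect_error(holm_bonferroni(c(0.1, 1.7)), "\\[0, 1\\]")
  # dominates raw p, dominated by plain Bonferroni, elementwise
  set.seed(6)
  p <- stats::runif(30)
  h <- holm_bonferroni(p)
  expect_true(all(h >= p))
  expect_true(all(h <= pmin(1, length(p) * p)))
})

test_that("Wilcoxon rank-sum: exact enumeration and tie handling", {
  r <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 2 / 6, tolerance = 1e-12)
  expect_equal(r$method, "exact")
  # exact path agrees with wilcox.test when there are no ties
  set.seed(9)
  x <- stats::rnorm(4); y <- stats::rnorm(5)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value,
               stats::wilcox.test(x, y)$p.value, tolerance = 1e-12)
  # all-tied input: p = 1 by convention
  expect_equal(wilcoxon_rank_sum(c(2, 2), c(2, 2, 2))$p_value, 1)
  # midranks under ties keep p in [0, 1] and the statistic sane
  rt <- wilcoxon_rank_sum(c(1, 2, 2, 7), c(2, 3, 3, 9, 9, 4, 4, 1, 5, 6, 8))
  expect_gte(rt$p_value, 0)
  expect_lte(rt$p_value, 1)
})

test_that("Kruskal-Wallis reduces to Wilcoxon for two groups", {
  set.seed(10)
  x <- stats::rnorm(25); y <- stats::rnorm(25, 0.4)
  kw <- kruskal_wallis(list(x, y))
  wx <- wilcoxon_rank_sum(x, y)
  expect_equal(kw$p_value, wx$p_value, tolerance = 1e-6)
  # all observations equal: H = 0
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1, 1)))$statistic, 0)
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "nonempty")
})

test_that("2x2 chi-square matches the closed form", {
  r <- chi_square_2x2(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$statistic, 20, tolerance = 1e-12)
  r2 <- chi_square_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  tb <- matrix(c(12, 5, 7, 9), 2)
  expect_equal(chi_square_2x2(tb)$statistic, chi_square_2x2(t(tb))$statistic,
               tolerance = 1e-12)
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margin")
})

test_that("univariate screen adjusts within the family and flags degeneracy", {
  set.seed(12)
  n <- 80
  f <- data.frame(x = stats::rnorm(n))
  tt <- stats::rexp(n, 1 / 300)
  ev <- rep(1L, n)
  one <- univariate_screen(f, tt, ev)
  expect_equal(one$p_adjusted, one$p_value)  # m = 1

  # a degenerate constant feature is flagged, not fatal
  f2 <- data.frame(x = stats::rnorm(n), const = rep(1, n))
  scr <- univariate_screen(f2, tt, ev)
  expect_true(scr$flagged[scr$feature == "const"])
  expect_false(anyNA(scr$p_adjusted[scr$feature == "x"]))

  # a strongly planted feature dominates the screen
  z <- stats::rnorm(150)
  s <- generate_survival(matrix(z, dimnames = list(NULL, "x")),
                         c(x = 1.2), baseline = 1 / 400,
                         censoring_rate = 0.1, seed = 44)
  feats <- data.frame(planted = z,
                      matrix(stats::rnorm(150 * 10), 150, 10,
                             dimnames = list(NULL, paste0("noise", 1:10))))
  scr2 <- univariate_screen(feats, s$os_days, s$event)
  expect_equal(scr2$feature[which.min(scr2$p_adjusted)], "planted")
  expect_lt(scr2$p_adjusted[scr2$feature == "planted"], 0.05)
})

test_that("family-wise error of the Holm screen stays controlled under the null", {
  fwer <- vapply(1:40, function(k) {
    set.seed(7000 + k)
    n <- 60
    f <- as.data.frame(matrix(stats::rnorm(n * 15), n, 15))
    tt <- stats::rexp(n, 1 / 300)
    scr <- univariate_screen(f, tt, rep(1L, n))
    any(scr$p_adjusted < 0.05, na.rm = TRUE)
  }, logical(1))
  # 40 Bernoulli(<=0.05) trials: >= 8 family-wise errors is implausible
  expect_lte(sum(fwer), 7)
})
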
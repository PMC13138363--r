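test_that("two-group dispatch picks the t-test family for Gaussian data", {
  set.seed(101)
  picks <- replicate(500, {
    r <- dispatch_two_groups(rnorm(30), rnorm(30))
    grepl("t-test", r$test)
  })
  expect_gte(mean(picks), 0.9)
})

test_that("two-group dispatch picks Mann-Whitney for heavily skewed data", {
  set.seed(102)
  picks <- replicate(500, {
    r <- dispatch_two_groups(rlnorm(30, sdlog = 1.5), rlnorm(30, sdlog = 1.5))
    r$test == "Mann-Whitney U"
  })
  expect_gte(mean(picks), 0.9)
})

test_that("identical samples are never significant and gates are reported", {
  set.seed(103)
  a <- rnorm(20)
  r <- dispatch_two_groups(a, a)
  expect_gt(r$p_value, 0.9)
  expect_length(r$gates$normality_p, 2L)
  # variance gate: unequal variances under normality switch to Welch
  set.seed(104)
  r2 <- dispatch_two_groups(rnorm(40, sd = 1), rnorm(40, sd = 5))
  expect_equal(r2$test, "Welch t-test")
  expect_lte(r2$gates$variance_p, 0.05)
})

test_that("tiny groups skip the normality gate and fall back nonparametric, flagged", {
  r <- dispatch_two_groups(c(1, 2), c(3, 4, 5))
  expect_equal(r$test, "Mann-Whitney U")
  expect_match(r$flags, "n < 3")
  expect_true(all(is.na(r$gates$normality_p)))
})

test_that("multi-group mapping: normal/homogeneous -> ANOVA + Bonferroni", {
  set.seed(105)
  g <- list(a = rnorm(50, 0), b = rnorm(50, 0.2), c = rnorm(50, 2))
  r <- dispatch_multi_groups(g)
  expect_equal(r$test, "ANOVA")
  expect_equal(r$posthoc, "Bonferroni pairwise t")
  expect_equal(nrow(r$pairwise), 3L)
  # Bonferroni is exactly min(1, raw * m)
  expect_equal(r$pairwise$p_adj, pmin(1, r$pairwise$p * 3))
  expect_true(all(r$pairwise$p_adj >= r$pairwise$p))
})

test_that("multi-group mapping: normal/heteroscedastic -> Welch ANOVA + Tamhane T2", {
  set.seed(106)
  g <- list(a = rnorm(50, sd = 1), b = rnorm(50, sd = 1), c = rnorm(50, sd = 4))
  r <- dispatch_multi_groups(g)
  expect_equal(r$test, "Welch ANOVA")
  expect_equal(r$posthoc, "Tamhane T2")
  # Sidak-style correction of pairwise Welch p-values
  expect_equal(r$pairwise$p_adj, pmin(1, 1 - (1 - r$pairwise$p)^3))
})

test_that("multi-group mapping: non-normal -> Kruskal-Wallis + Dunn", {
  set.seed(107)
  g <- list(a = rlnorm(50, sdlog = 1.5), b = rlnorm(50, sdlog = 1.5),
            c = rlnorm(50, sdlog = 1.5))
  r <- dispatch_multi_groups(g)
  expect_equal(r$test, "Kruskal-Wallis")
  expect_equal(r$posthoc, "Dunn")
  expect_true(all(r$pairwise$p_adj >= r$pairwise$p))
})

test_that("dispatch is a pure function of the data", {
  set.seed(108)
  g <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  r1 <- dispatch_multi_groups(g)
  r2 <- dispatch_multi_groups(g)
  expect_identical(test_report_json(r1), test_report_json(r2))
})

test_that("rank tests are invariant under strictly monotone transforms", {
  set.seed(109)
  a <- rlnorm(25, sdlog = 2); b <- rlnorm(25, sdlog = 2) * 3
  r1 <- dispatch_two_groups(a, b)
  r2 <- dispatch_two_groups(a^3, b^3)  # cubing keeps the data heavily skewed
  expect_equal(r1$test, "Mann-Whitney U")
  expect_equal(r2$test, "Mann-Whitney U")
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$p_value, r2$p_value)
  g <- list(a = a, b = b, c = rlnorm(25, sdlog = 2))
  d1 <- dunn_posthoc(g)
  d2 <- dunn_posthoc(lapply(g, function(x) x^3))
  expect_equal(d1$statistic, d2$statistic)
})

test_that("Dunn z statistics match a hand-computed small example", {
  # groups {1,2,3}, {4,5,6}, {7,8,9}: no ties, pooled ranks 1..9
  # mean ranks 2, 5, 8; N = 9; sigma^2 = N(N+1)/12 = 7.5
  # z_12 = (2-5)/sqrt(7.5 * (1/3+1/3)) = -3/sqrt(5)
  g <- list(a = c(1, 2, 3), b = c(4, 5, 6), c = c(7, 8, 9))
  d <- dunn_posthoc(g)
  expect_equal(d$statistic[d$group1 == "a" & d$group2 == "b"], -3 / sqrt(5))
  expect_equal(d$statistic[d$group1 == "a" & d$group2 == "c"], -6 / sqrt(5))
  expect_equal(d$p, 2 * pnorm(-abs(d$statistic)))
  # tie correction: duplicating a value lowers the variance term
  gt <- list(a = c(1, 1, 2), b = c(3, 4, 5), c = c(6, 7, 8))
  dt <- dunn_posthoc(gt)
  expect_true(all(is.finite(dt$statistic)))
})

test_that("Tamhane T2 matches pairwise Welch t-tests with Sidak correction", {
  set.seed(110)
  g <- list(a = rnorm(15, sd = 1), b = rnorm(25, sd = 3), c = rnorm(10, sd = 0.5))
  tt <- tamhane_t2(g)
  w <- t.test(g$a, g$b)  # Welch by default
  row <- tt[tt$group1 == "a" & tt$group2 == "b", ]
  expect_equal(row$statistic, unname(w$statistic))
  expect_equal(row$df, unname(w$parameter))
  expect_equal(row$p_adj, 1 - (1 - w$p.value)^3)
})

test_that("AUC handles rectangle, triangle, and both study time grids", {
  expect_equal(auc_trapezoid(c(0, 120), c(100, 100)), 12000)
  expect_equal(auc_trapezoid(c(0, 120), c(0, 120)), 7200)
  # composite over study grids
  fasting_grid <- c(0, 15, 40, 60, 120)
  refeed_grid <- c(0, 15, 30, 60, 120)
  g <- c(80, 250, 300, 220, 150)
  expect_gt(auc_trapezoid(fasting_grid, g), 0)
  expect_gt(auc_trapezoid(refeed_grid, g), 0)
  # incremental subtracts the 0-min baseline
  expect_equal(auc_trapezoid(c(0, 120), c(100, 100), type = "incremental"), 0)
})

test_that("AUC agrees with a fine-grid piecewise-linear integration oracle", {
  fine_oracle <- function(times, glucose, n = 1e6) {
    tt <- seq(times[1], times[length(times)], length.out = n)
    mid <- (tt[-1] + tt[-n]) / 2
    sum(approx(times, glucose, xout = mid)$y * diff(tt))
  }
  curve <- list(t = c(0, 15, 40, 60, 120), g = c(80, 250, 300, 220, 150))
  expect_equal(auc_trapezoid(curve$t, curve$g),
               fine_oracle(curve$t, curve$g), tolerance = 1e-9)
  set.seed(111)
  for (i in 1:5) {
    t <- c(0, sort(sample(1:119, 4)), 120)
    g <- runif(6, 50, 400)
    expect_equal(auc_trapezoid(t, g), fine_oracle(t, g), tolerance = 1e-9)
  }
})

test_that("AUC validates its input grid", {
  expect_error(auc_trapezoid(c(0), c(100)), "at least 2")
  expect_error(auc_trapezoid(c(0, 10, 10), c(1, 2, 3)), "strictly increasing")
  expect_error(auc_trapezoid(c(5, 10), c(1, 2)), "start at 0")
  expect_error(auc_trapezoid(c(0, 10), c(1, -2)), "negative")
})

test_that("AUC is linear in glucose and additive over abutting intervals", {
  t <- c(0, 15, 40, 60, 120); g <- c(80, 250, 300, 220, 150)
  expect_equal(auc_trapezoid(t, 2 * g), 2 * auc_trapezoid(t, g))
  a1 <- auc_trapezoid(c(0, 15, 40), c(80, 250, 300))
  a2 <- auc_trapezoid(c(0, 20, 80), c(300, 220, 150))  # shifted second half
  whole <- auc_trapezoid(t, g)
  expect_equal(a1 + a2, whole)
})
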
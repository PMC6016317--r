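test_that("one-way ANOVA reproduces hand-computed and identity cases", {
  # {1,2,3},{2,3,4},{3,4,5}: SSB = 6, SSW = 6 -> F = 3 with df (2, 6)
  r <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(r$statistic, 3, tolerance = 1e-12)
  expect_equal(r$df, c(2, 6))

  # identical means -> F = 0
  r0 <- one_way_anova(list(c(1, 3), c(0, 4), c(-1, 5)))
  expect_equal(r0$statistic, 0, tolerance = 1e-12)

  # two groups: F equals the squared pooled t
  set.seed(5)
  a <- rnorm(9); b <- rnorm(7, mean = 0.8)
  f2 <- one_way_anova(list(a, b))
  tt <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(f2$statistic, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(f2$p_value, tt$p.value, tolerance = 1e-9)

  expect_error(one_way_anova(list(c(1, 2))), ">= 2")
  expect_error(one_way_anova(list(c(1, 2), c(3))), "n >= 2")
})

test_that("raw-data and summary-statistics ANOVA routes agree with aov", {
  set.seed(6)
  groups <- list(rnorm(7, 1), rnorm(6, 1.4), rnorm(6, 0.7))
  mine <- one_way_anova(groups)
  summ <- one_way_anova_summary(sapply(groups, mean), sapply(groups, sd),
                                lengths(groups))
  expect_equal(mine$statistic, summ$statistic, tolerance = 1e-12)

  d <- data.frame(y = unlist(groups),
                  g = factor(rep(seq_along(groups), lengths(groups))))
  ref <- summary(stats::aov(y ~ g, data = d))[[1]]
  expect_equal(mine$statistic, ref[["F value"]][1], tolerance = 1e-9)
  expect_equal(mine$p_value, ref[["Pr(>F)"]][1], tolerance = 1e-9)
})

test_that("ANOVA F is invariant to location and scale shifts", {
  set.seed(7)
  groups <- list(rnorm(8), rnorm(6, 0.5), rnorm(7, 1))
  f1 <- one_way_anova(groups)$statistic
  shifted <- lapply(groups, function(g) 3.2 * g + 11)
  expect_equal(one_way_anova(shifted)$statistic, f1, tolerance = 1e-9)
})

test_that("Bonferroni post hoc multiplies raw p by the comparison count", {
  set.seed(8)
  groups <- list(a = rnorm(7), b = rnorm(6, 2), c = rnorm(6))
  ph <- bonferroni_pairwise(groups)
  expect_equal(nrow(ph), 3)
  expect_equal(ph$p_adjusted, pmin(1, ph$p_raw * 3), tolerance = 1e-12)
  expect_true(all(ph$p_adjusted <= 1))
  # pooled-SD raw p agrees with pairwise.t.test
  d <- data.frame(y = unlist(groups),
                  g = factor(rep(names(groups), lengths(groups))))
  ref <- stats::pairwise.t.test(d$y, d$g, p.adjust.method = "none",
                                pool.sd = TRUE)$p.value
  expect_equal(ph$p_raw[ph$group1 == "a" & ph$group2 == "b"],
               ref["b", "a"], tolerance = 1e-9)
  # identical groups -> adjusted p capped at 1
  same <- bonferroni_pairwise(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_true(all(same$p_adjusted == 1))
})

test_that("two-way ANOVA handles balanced, reduced and missing-cell designs", {
  # balanced additive data with zero noise: interaction SS = 0
  a <- factor(rep(1:3, each = 8))
  b <- factor(rep(rep(1:2, each = 4), 3))
  y_add <- as.numeric(a) * 2 + as.numeric(b) * 5
  tw <- two_way_anova(y_add, a, b)
  expect_lt(tw$interaction$ss, 1e-9)

  # one-level second factor reduces to the one-way F
  set.seed(9)
  y <- rnorm(24, mean = as.numeric(a))
  red <- two_way_anova(y, a, factor(rep(1, 24)))
  ref <- one_way_anova(split(y, a))
  expect_equal(red$factor_a$statistic, ref$statistic, tolerance = 1e-9)

  # balanced random design: Type II equals classical aov and SS decompose
  y2 <- rnorm(24, mean = as.numeric(a) + 0.5 * as.numeric(b))
  tw2 <- two_way_anova(y2, a, b)
  ref2 <- summary(stats::aov(y2 ~ a * b))[[1]]
  expect_equal(tw2$factor_a$statistic, ref2[["F value"]][1], tolerance = 1e-9)
  expect_equal(tw2$interaction$statistic, ref2[["F value"]][3], tolerance = 1e-9)
  ss_total <- sum((y2 - mean(y2))^2)
  expect_equal(tw2$factor_a$ss + tw2$factor_b$ss + tw2$interaction$ss +
               tw2$residual_ss, ss_total, tolerance = 1e-9)

  # empty cell: interaction flagged, main effects still reported
  keep <- !(a == 3 & b == 2)
  tw3 <- two_way_anova(y2[keep], a[keep], b[keep])
  expect_equal(tw3$interaction$note, "missing cells")
  expect_true(is.finite(tw3$factor_a$statistic))
})

test_that("Kruskal-Wallis H matches the hand rank computation", {
  r <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(r$statistic, 3.8571, tolerance = 1e-3)
  expect_equal(r$df, 1)

  # complete ties give H = 0, not an error
  expect_equal(kruskal_wallis(list(c(2, 2), c(2, 2, 2)))$statistic, 0)

  # rank invariance under strictly monotone transforms
  set.seed(10)
  g <- list(rnorm(8), rnorm(7, 1), rnorm(6, 2))
  h1 <- kruskal_wallis(g)$statistic
  h2 <- kruskal_wallis(lapply(g, function(x) exp(x)))$statistic
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("Pearson correlation matches hand computation and a permutation null", {
  expect_equal(pearson_r(1:5, 2 * (1:5) + 1)$r, 1, tolerance = 1e-12)
  r <- pearson_r(c(1, 2, 3), c(1, 2, 4))
  expect_equal(r$r, 0.98198, tolerance = 1e-4)

  set.seed(12)
  x <- rnorm(10); y <- 0.5 * x + rnorm(10)
  res <- pearson_r(x, y)
  r_obs <- abs(stats::cor(x, y))
  perm <- mean(replicate(1e4, abs(stats::cor(x, sample(y)))) >= r_obs)
  expect_equal(res$p_value, perm, tolerance = 0.02)

  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(pearson_r(1:2, 1:2), "n >= 3")

  # affine invariance per variable
  set.seed(13)
  x2 <- rnorm(12); y2 <- rnorm(12)
  expect_equal(pearson_r(2 * x2 - 3, -0.5 * y2 + 7)$r,
               -pearson_r(x2, y2)$r, tolerance = 1e-12)
})

test_that("Lilliefors normality check behaves under null and gross misfit", {
  # seeded normal draws rarely rejected
  set.seed(14)
  pvals <- replicate(100, ks_normality(rnorm(1000))$p_value)
  expect_gte(mean(pvals > 0.05), 0.95)

  # a uniform grid is decisively non-normal at n = 1000
  expect_lt(ks_normality(seq(0, 1, length.out = 1000))$p_value, 0.05)

  expect_error(ks_normality(c(1, 2)), "n >= 4")
  expect_error(ks_normality(rep(1, 10)), "constant")
})
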
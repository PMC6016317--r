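#' Named test-statistic container
#' @param test_name Name of the test.
#' @param statistic Statistic value (F, H, D, t, ...).
#' @param df Degrees of freedom (single value or pair).
#' @param p_value Two-sided p-value.
#' @param groups Optional group labels.
#' @param note Optional condition note (e.g. missing-cell flag).
#' @return A `stat_result` list.
#' @keywords internal
stat_result <- function(test_name, statistic, df, p_value, groups = NULL,
                        note = NULL, ss = NULL) {
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, groups = groups, note = note, ss = ss),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(x$df, collapse = ", ")
  cat(sprintf("%s: statistic = %.4f, df = (%s), p = %.4g%s\n",
              x$test_name, x$statistic, dfs, x$p_value,
              if (!is.null(x$note)) paste0(" [", x$note, "]") else ""))
  invisible(x)
}

#' Kolmogorov--Smirnov normality check (Lilliefors)
#'
#' One-sample test of normality against a normal with mean and SD estimated
#' from the sample. Because the parameters are estimated, Lilliefors critical
#' values are used (a plain KS test against the fitted normal would be
#' anti-conservative).
#'
#' @param sample Numeric vector, n >= 4, non-constant.
#' @return A `stat_result` with the D statistic.
#' @export
ks_normality <- function(sample) {
  sample <- as.numeric(sample)
  if (length(sample) < 4L) stop("normality check needs n >= 4", call. = FALSE)
  if (stats::sd(sample) == 0) stop("constant sample: normality test degenerate", call. = FALSE)
  fit <- nortest::lillie.test(sample)
  stat_result("Lilliefors (Kolmogorov-Smirnov) normality",
              unname(fit$statistic), length(sample), fit$p.value)
}

#' One-way ANOVA from summary statistics
#'
#' F computed from the sums-of-squares identities given only per-group means,
#' SDs and sizes: `SS_between = sum n_i (m_i - m)^2`,
#' `SS_within = sum (n_i - 1) s_i^2`, `F = MS_between / MS_within` with
#' df (k-1, N-k). This is the single computational route for the raw-data
#' version too, so the two always agree exactly.
#'
#' @param means,sds,ns Per-group means, standard deviations and sizes.
#' @return A `stat_result` with the F statistic.
#' @export
one_way_anova_summary <- function(means, sds, ns) {
  k <- length(means)
  if (k < 2L || length(sds) != k || length(ns) != k) {
    stop("need >= 2 groups with matching means/sds/ns", call. = FALSE)
  }
  if (any(ns < 2)) stop("each group needs n >= 2", call. = FALSE)
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df1 <- k - 1L
  df2 <- N - k
  if (ssw <= 0) stop("zero within-group variance: F undefined", call. = FALSE)
  f <- (ssb / df1) / (ssw / df2)
  stat_result("one-way ANOVA", f, c(df1, df2),
              stats::pf(f, df1, df2, lower.tail = FALSE))
}

#' One-way analysis of variance
#'
#' @param groups List of numeric vectors (>= 2 groups, each n >= 2).
#' @return A `stat_result` with F, df (k-1, N-k), p.
#' @examples
#' one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))  # F = 3, df (2, 6)
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need a list of >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2", call. = FALSE)
  res <- one_way_anova_summary(
    vapply(groups, mean, numeric(1)),
    vapply(groups, stats::sd, numeric(1)),
    lengths(groups)
  )
  res$groups <- names(groups)
  res
}

#' Bonferroni-adjusted pairwise comparisons
#'
#' All k(k-1)/2 pairwise t-tests using the pooled within-group mean square
#' from the omnibus one-way ANOVA (error df N-k), with each raw p multiplied
#' by the number of comparisons and capped at 1.
#'
#' @param groups List of numeric vectors.
#' @param alpha Significance level used for the `significant` flag
#'   (default 0.05).
#' @return Data frame with one row per pair: `group1`, `group2`, `t`, `df`,
#'   `p_raw`, `p_adjusted`, `significant`.
#' @export
bonferroni_pairwise <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) stop("need a list of >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2L)) stop("each group needs n >= 2", call. = FALSE)
  k <- length(groups)
  labs <- if (!is.null(names(groups))) names(groups) else paste0("g", seq_len(k))
  ns <- lengths(groups)
  N <- sum(ns)
  msw <- sum((ns - 1) * vapply(groups, stats::var, numeric(1))) / (N - k)
  m <- vapply(groups, mean, numeric(1))
  pairs <- utils::combn(k, 2)
  ncomp <- ncol(pairs)
  out <- data.frame(
    group1 = labs[pairs[1, ]], group2 = labs[pairs[2, ]],
    t = NA_real_, df = N - k, p_raw = NA_real_, p_adjusted = NA_real_,
    significant = NA, stringsAsFactors = FALSE
  )
  for (j in seq_len(ncomp)) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt(msw * (1 / ns[i1] + 1 / ns[i2]))
    tval <- (m[i1] - m[i2]) / se
    p <- 2 * stats::pt(abs(tval), N - k, lower.tail = FALSE)
    out$t[j] <- tval
    out$p_raw[j] <- p
    out$p_adjusted[j] <- min(1, p * ncomp)
    out$significant[j] <- out$p_adjusted[j] < alpha
  }
  out
}

#' Two-way analysis of variance (Type II)
#'
#' Factorial ANOVA of `value ~ factor_a * factor_b` with Type-II sums of
#' squares, suited to the unbalanced designs that arise when event counts
#' differ across group and seizure phase. When a factor has a single level
#' the analysis reduces to a one-way ANOVA on the other factor. When any
#' design cell is empty the interaction cannot be estimated: the additive
#' model is fitted instead and the interaction is flagged missing.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factors (or coercible) of the same length.
#' @return Named list of `stat_result`s `factor_a`, `factor_b`,
#'   `interaction` (the latter with `note = "missing cells"` and NA
#'   statistic when cells are empty), each carrying its Type-II sum of
#'   squares in `$ss`, plus `residual_ss`.
#' @export
two_way_anova <- function(values, factor_a, factor_b) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  stopifnot(length(values) == length(a), length(values) == length(b))
  if (nlevels(a) < 2L && nlevels(b) < 2L) {
    stop("need >= 2 levels in at least one factor", call. = FALSE)
  }
  if (nlevels(b) < 2L || nlevels(a) < 2L) {
    act <- if (nlevels(a) >= 2L) a else b
    one <- one_way_anova(split(values, act))
    empty <- stat_result("two-way ANOVA (single-level factor)", NA_real_,
                         NA_integer_, NA_real_, note = "factor has one level")
    res <- list(factor_a = if (nlevels(a) >= 2L) one else empty,
                factor_b = if (nlevels(b) >= 2L) one else empty,
                interaction = empty)
    return(res)
  }
  d <- data.frame(y = values, A = a, B = b)
  cells <- table(d$A, d$B)
  has_empty <- any(cells == 0L)
  fml <- if (has_empty) y ~ A + B else y ~ A * B
  fit <- stats::lm(fml, data = d)
  # car's Type-II table refuses an exactly perfect fit (zero residual SS);
  # the sequential table still yields the SS decomposition in that case,
  # and for the perfect-fit case the design must be balanced for F to have
  # meant anything anyway
  tab <- tryCatch(car::Anova(fit, type = 2),
                  error = function(e) suppressWarnings(stats::anova(fit)))
  i_res <- match("Residuals", rownames(tab))
  pull <- function(term) {
    i <- match(term, rownames(tab))
    stat_result(paste("two-way ANOVA:", term), tab[i, "F value"],
                c(tab[i, "Df"], tab[i_res, "Df"]), tab[i, "Pr(>F)"],
                ss = tab[i, "Sum Sq"])
  }
  res <- list(factor_a = pull("A"), factor_b = pull("B"))
  res$interaction <- if (has_empty) {
    stat_result("two-way ANOVA: A:B", NA_real_, NA_integer_, NA_real_,
                note = "missing cells")
  } else {
    pull("A:B")
  }
  res$residual_ss <- tab[i_res, "Sum Sq"]
  res
}

#' Kruskal--Wallis rank test
#'
#' Rank-based H statistic with tie correction, df = k - 1. All-identical
#' values give H = 0 (complete ties), not an error.
#'
#' @param groups List of numeric vectors (>= 2 groups, total n >= 3).
#' @return A `stat_result` with the H statistic.
#' @export
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) stop("need a list of >= 2 groups", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3L) stop("need total n >= 3", call. = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::sd(x) == 0) {
    return(stat_result("Kruskal-Wallis", 0, length(groups) - 1L, 1,
                       groups = names(groups)))
  }
  fit <- stats::kruskal.test(x, g)
  stat_result("Kruskal-Wallis", unname(fit$statistic),
              unname(fit$parameter), fit$p.value, groups = names(groups))
}

#' Pearson correlation between AD duration and band power
#'
#' Sample Pearson r with a two-sided p-value from the t transform
#' `t = r sqrt((n-2)/(1-r^2))`.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, both non-constant.
#' @return A `correlation_result`: `r`, `n`, `p_value`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("correlation needs n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input: correlation undefined", call. = FALSE)
  }
  fit <- stats::cor.test(x, y, method = "pearson")
  structure(list(r = unname(fit$estimate), n = length(x),
                 p_value = fit$p.value),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f (n = %d, p = %.4g)\n", x$r, x$n, x$p_value))
  invisible(x)
}
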
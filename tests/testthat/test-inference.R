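test_that("paired t test behaves classically", {
  x <- c(1, 2, 3, 4, 5)
  expect_error(paired_t(x, x), "degenerate")
  withr::with_seed(1, {
    y <- x + 1 + rnorm(5, 0, 1e-6)
    res <- paired_t(y, x)
    expect_gt(res$value, 1e4)
    expect_lt(res$p, 1e-10)
    expect_equal(res$df, 4)
  })
  # oracle: matches the closed-form t on the differences
  withr::with_seed(2, {
    a <- rnorm(12)
    b <- rnorm(12)
    d <- a - b
    expect_equal(paired_t(a, b)$value, mean(d) / (sd(d) / sqrt(12)))
  })
})

test_that("signed-rank Z matches the exact distribution for small n", {
  x <- 1:14
  expect_equal(wilcoxon_paired(x, x)$degenerate, TRUE)
  # strictly positive differences: maximal Z
  y <- x - seq(0.5, 7.5, length.out = 14)
  res <- wilcoxon_paired(x, y)
  mu <- 14 * 15 / 4
  sg <- sqrt(14 * 15 * 29 / 24)
  expect_equal(res$value, (14 * 15 / 2 - mu) / sg)
  expect_lt(res$p, 0.001)
  # antisymmetry
  expect_equal(wilcoxon_paired(y, x)$value, -res$value)
  # normal-approximation p tracks the exact signed-rank p on random input
  withr::with_seed(42, {
    for (i in 1:20) {
      a <- rnorm(14)
      b <- rnorm(14, 0.3)
      approx_p <- wilcoxon_paired(a, b)$p
      exact_p <- wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
      expect_lt(abs(approx_p - exact_p), 0.08)
    }
  })
})

test_that("normalizing transforms behave as documented", {
  x <- withr::with_seed(3, rexp(40))
  expect_equal(apply_transform(x, "arcsinh"), asinh(x))
  oq <- apply_transform(x, "orderquant")
  expect_equal(order(oq), order(x))           # rank preserving
  expect_lt(abs(mean(oq)), 0.05)              # centred normal scores
  expect_equal(sort(oq), qnorm((1:40 - 0.5) / 40))
  yj <- apply_transform(x, "yeojohnson")
  expect_equal(order(yj), order(x))
  expect_gt(shapiro.test(yj)$p.value, shapiro.test(x)$p.value)
  expect_identical(apply_transform(x, "none"), x)
})

test_that("extreme outliers follow the 3 x IQR rule with type-7 quartiles", {
  out <- extreme_outliers(c(1, 2, 3, 4, 100))
  expect_equal(attr(out, "q1"), 2)
  expect_equal(attr(out, "q3"), 4)
  expect_equal(out$value, 100)
  expect_equal(out$bound, "upper")
  expect_equal(nrow(extreme_outliers(rep(5, 10))), 0)
  expect_equal(nrow(extreme_outliers(c(-2, -1, 0, 1, 2))), 0)
  # flags invariant to ordering
  x <- c(1, 2, 3, 4, 100, -50)
  a <- extreme_outliers(x)
  b <- extreme_outliers(rev(x))
  expect_setequal(a$value, b$value)
})

test_that("p-value corrections match hand-computed step-up values", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(adjust_pvalues(rep(0.03, 10), "bonferroni"), rep(0.3, 10))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(0.2, "bonferroni"), 0.2)
  p <- withr::with_seed(4, runif(20))
  adj <- adjust_pvalues(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0,1\\]")
})

test_that("repeated-measures ANOVA recovers the condition effect as t^2", {
  withr::with_seed(7, {
    d <- expand.grid(subject = factor(1:14), condition = c("inc", "exc"),
                     segment = paste0("s", 1:3))
    d$value <- rnorm(nrow(d)) + rep(rnorm(14), 6) +
      ifelse(d$condition == "exc", 0.5, 0)
    res <- rm_anova_2way(d)
    expect_equal(res$effect, c("Condition", "Segment", "Condition:Segment"))
    expect_equal(res$DFn, c(1, 2, 2))
    expect_equal(res$DFd, c(13, 26, 26))
    # independent oracle: F(condition) = paired-t^2 on subject means
    cm <- tapply(d$value, list(d$subject, d$condition), mean)
    tt <- t.test(cm[, "inc"], cm[, "exc"], paired = TRUE)
    expect_equal(res$F[1], unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p[1], tt$p.value, tolerance = 1e-9)
    expect_true(all(res$pes >= 0 & res$pes <= 1))
    expect_true(all(res$gg_eps > 0.5 & res$gg_eps <= 1 + 1e-9))
  })
})

test_that("ANOVA F is invariant to location shifts and rejects bad input", {
  withr::with_seed(8, {
    d <- expand.grid(subject = factor(1:10), condition = c("a", "b"),
                     segment = paste0("s", 1:3))
    d$value <- rnorm(nrow(d))
    f1 <- rm_anova_2way(d)$F
    d2 <- d
    d2$value <- d$value + 100
    expect_equal(rm_anova_2way(d2)$F, f1, tolerance = 1e-9)
    d3 <- d
    d3$value <- 3 * d$value - 7
    expect_equal(rm_anova_2way(d3)$F, f1, tolerance = 1e-9)
    expect_error(rm_anova_2way(d[-1, ]), "unbalanced")
  })
})

test_that("the ANOVA family adjusts across all emotions and effects", {
  co <- generate_cohort(small_spec(seed = 21, duration_s = c(125, 135)))
  trimmed <- lapply(co$recordings, trim_lead)
  aucs <- cohort_aucs(trimmed)
  fam <- rm_anova_by_emotion(aucs)
  expect_equal(nrow(fam), 21)
  expect_true(all(fam$p_adjusted >= fam$p - 1e-12))
  expect_equal(fam$p_adjusted, adjust_pvalues(fam$p))
  fam2 <- rm_anova_by_emotion(aucs, include_outliers = FALSE)
  expect_true(all(fam2$n_subjects <= fam$n_subjects))
})

test_that("Spearman matrices report rho, raw and corrected p", {
  x <- 1:20
  res <- spearman_matrix(data.frame(a = x, b = x^3, c = rev(x)))
  expect_equal(res$rho["a", "b"], 1)
  expect_equal(res$rho["a", "c"], -1)
  expect_true(all(res$p_adjusted >= res$p, na.rm = TRUE))
  w <- capture_warnings(spearman_matrix(data.frame(a = x, k = rep(1, 20))))
  expect_match(w, "constant", all = FALSE)
  # null: independent columns rarely show |rho| > 0.1 at n = 500
  withr::with_seed(11, {
    hits <- replicate(40, {
      m <- spearman_matrix(data.frame(u = runif(500), v = runif(500)))
      abs(m$rho["u", "v"]) > 0.1
    })
    expect_lte(mean(hits), 0.05)
  })
  # two-table mode corrects over all pairs
  withr::with_seed(12, {
    left <- data.frame(a = rnorm(30), b = rnorm(30))
    right <- data.frame(u = rnorm(30), v = rnorm(30), w = rnorm(30))
    res2 <- spearman_matrix(left, right)
    expect_equal(dim(res2$rho), c(2, 3))
    expect_false(anyNA(res2$p_adjusted))
  })
})
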
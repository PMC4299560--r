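test_that("pearson_regression matches hand-evaluated and stats oracles", {
  x <- 1:10
  r1 <- pearson_regression(x, 2 * x + 1)
  expect_equal(r1$r, 1)
  expect_equal(r1$slope, 2)
  expect_equal(r1$intercept, 1)

  expect_equal(pearson_regression(x, -x)$r, -1)

  # direct evaluation of the sum formulas gives r = 0.6
  r2 <- pearson_regression(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r2$r, 0.6)

  set.seed(3)
  a <- rnorm(40); b <- 0.5 * a + rnorm(40)
  ct <- cor.test(a, b)
  fit <- lm(b ~ a)
  out <- pearson_regression(a, b)
  expect_equal(out$r, unname(ct$estimate))
  expect_equal(out$p_value, ct$p.value)
  expect_equal(out$slope, unname(coef(fit)[2]))
  expect_equal(out$intercept, unname(coef(fit)[1]))

  expect_error(pearson_regression(rep(1, 5), 1:5),
               class = "ctild_undefined_correlation_error")
})

test_that("icc_two_way matches an independent mean-squares oracle", {
  m <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8), nrow = 4)  # 4 subjects x 3 raters
  n <- nrow(m); k <- ncol(m)
  # independent oracle via aov() sums of squares
  df <- data.frame(y = as.vector(m),
                   subj = factor(rep(1:n, k)),
                   rater = factor(rep(1:k, each = n)))
  ss <- summary(aov(y ~ subj + rater, data = df))[[1]]
  msr <- ss["subj", "Mean Sq"]; msc <- ss["rater", "Mean Sq"]
  mse <- ss["Residuals", "Mean Sq"]
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc_two_way(m), icc_oracle)

  # constant shift: consistency is exactly 1, agreement below it
  s <- c(2, 9, 4, 12, 7)
  shifted <- cbind(s, s + 3)
  expect_equal(icc_two_way(shifted, type = "consistency"), 1)
  expect_lt(icc_two_way(shifted, type = "agreement"), 1)
  expect_gt(icc_two_way(shifted, type = "agreement"), 0.5)

  expect_error(icc_two_way(cbind(rep(1, 4), rep(1, 4))),
               class = "ctild_degenerate_icc_error")
})

test_that("icc_two_way recovers the analytic ICC on simulated readers", {
  set.seed(11)
  sb <- 4; se <- 2
  truth <- sb^2 / (sb^2 + se^2)
  subj <- rnorm(3000, 0, sb)
  ratings <- cbind(subj + rnorm(3000, 0, se), subj + rnorm(3000, 0, se))
  expect_lt(abs(icc_two_way(ratings) - truth), 0.02)
})

test_that("compare_groups reproduces textbook t and chi-square values", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3), kind = "t_test")
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # pooled-variance hand computation: t = -3 / sqrt(2/3)
  out <- compare_groups(c(1, 2, 3), c(4, 5, 6), kind = "t_test")
  expect_equal(out$statistic, -3 / sqrt(2 / 3))
  expect_equal(round(out$statistic, 3), -3.674)
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(out$statistic, unname(tt$statistic))
  expect_equal(out$p_value, tt$p.value)

  flat <- matrix(10, 2, 2)
  expect_equal(compare_groups(flat, kind = "chi_square")$statistic, 0)

  tab <- matrix(c(12, 5, 7, 19), 2, 2)
  ours <- compare_groups(tab, kind = "chi_square")
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(ours$statistic, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)
})

test_that("ROC handles separable and uninformative scores", {
  scores <- c(1, 2, 3, 10, 11, 12)
  labels <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  roc <- roc_analysis(scores, labels)
  expect_equal(roc$auc, 1)
  opt <- roc$points[roc$points$criterion == roc$optimal_threshold, ]
  expect_equal(opt$sensitivity, 1)
  expect_equal(opt$specificity, 1)

  set.seed(14)
  s2 <- rnorm(2000); l2 <- sample(c(TRUE, FALSE), 2000, replace = TRUE)
  expect_lt(abs(roc_analysis(s2, l2)$auc - 0.5), 0.04)

  expect_error(roc_analysis(1:5, rep(TRUE, 5)),
               class = "ctild_validation_error")
})

test_that("trapezoidal AUC equals the Mann-Whitney pair-counting oracle", {
  set.seed(21)
  for (i in 1:30) {
    n <- sample(6:50, 1)
    scores <- sample(round(rnorm(n, 10, 4), sample(0:1, 1)))  # force ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    roc <- roc_analysis(scores, labels)
    expect_equal(roc$auc, mw_auc_oracle(scores, labels), tolerance = 1e-12)
  }
})

test_that("ROC invariances hold: staircase, transform, complement", {
  set.seed(22)
  scores <- round(rexp(60, 0.1))
  labels <- runif(60) < plogis((scores - 10) / 5)
  labels[1:2] <- c(TRUE, FALSE)
  roc <- roc_analysis(scores, labels)
  expect_true(all(diff(roc$points$sensitivity) <= 0))
  expect_true(all(diff(roc$points$specificity) >= 0))
  # invariance under strictly increasing transform
  roc2 <- roc_analysis(exp(scores / 10), labels)
  expect_equal(roc2$auc, roc$auc)
  # complement identity with ties handled symmetrically
  roc3 <- roc_analysis(-scores, labels)
  expect_equal(roc$auc + roc3$auc, 1)
  # Hanley-McNeil SE is positive and sane
  expect_gt(roc$auc_se, 0)
  expect_lt(roc$auc_se, 0.5)
})

test_that("criterion table matches direct confusion arithmetic", {
  # 41 positives (31 above the cutoff), 39 negatives (1 above)
  scores <- c(rep(25, 31), rep(15, 10), rep(25, 1), rep(15, 38))
  labels <- c(rep(TRUE, 41), rep(FALSE, 39))
  roc <- roc_analysis(scores, labels)
  tab <- criterion_table(roc)
  row <- tab[tab$criterion == 15, ]
  expect_equal(round(row$sensitivity_pct, 2), 75.61)  # 31/41
  expect_equal(round(row$specificity_pct, 2), 97.44)  # 38/39
  expect_equal(row$lr_pos, (31 / 41) / (1 / 39))
  expect_equal(row$ppv_pct, 100 * 31 / 32)
  expect_equal(row$npv_pct, 100 * 38 / 48)

  # perfect row: -LR 0, predictive values 100
  sep <- roc_analysis(c(1, 1, 9, 9), c(FALSE, FALSE, TRUE, TRUE))
  st <- criterion_table(sep)
  perfect <- st[st$criterion == 1, ]
  expect_equal(perfect$lr_neg, 0)
  expect_equal(perfect$ppv_pct, 100)
  expect_equal(perfect$npv_pct, 100)
  expect_true(is.na(perfect$lr_pos))  # omitted at specificity 100%

  # criterion-table sensitivity ordering
  expect_true(all(diff(tab$sensitivity_pct) <= 0))
})

test_that("Clopper-Pearson intervals match the exact beta quantiles", {
  # 0 of 39 successes: closed-form upper bound 1 - alpha^(1/n)
  ci <- clopper_pearson(0, 39)
  expect_equal(unname(ci["lower"]), 0)
  expect_equal(unname(ci["upper"]), 1 - 0.025^(1 / 39))
  # generic cases against binom.test
  for (cs in list(c(31, 41), c(38, 39), c(5, 10))) {
    ours <- clopper_pearson(cs[1], cs[2])
    ref <- binom.test(cs[1], cs[2])$conf.int
    expect_equal(unname(ours), as.numeric(ref))
  }
})
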
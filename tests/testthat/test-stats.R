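test_that("two-sample test covers degenerate and clear-cut inputs", {
  same <- c(1, 2, 3)
  res <- two_sample_test(same, same)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res2 <- two_sample_test(c(1, 2, 3), c(11, 12, 13))
  expect_lt(res2$p_value, 0.01)
  expect_equal(two_sample_test(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_error(two_sample_test(1, c(1, 2)))
  # Student variant agrees with the pooled t test
  set.seed(4)
  x <- rnorm(20); y <- rnorm(25, 0.5)
  expect_equal(two_sample_test(x, y, "student")$p_value,
               t.test(x, y, var.equal = TRUE)$p.value)
})

test_that("simulated FAI groups separate at p < 0.001 in almost all seeds", {
  p <- vapply(1:200, function(s) {
    set.seed(s)
    two_sample_test(rnorm(52, -78.1, 6.2), rnorm(65, -87.2, 7.3))$p_value
  }, numeric(1))
  expect_gte(mean(p < 0.001), 0.99)
})

test_that("categorical test recomputes published-style 2x2 tables", {
  # hypertension counts: 31/65 vs 28/52
  res <- categorical_test(matrix(c(31, 28, 34, 24), 2, 2))
  expect_equal(res$method, "chisq")
  expect_lt(abs(res$p_value - 0.51), 0.02)
  ident <- categorical_test(matrix(c(30, 30, 20, 20), 2, 2))
  expect_equal(ident$p_value, 1, tolerance = 1e-9)
  perfect <- categorical_test(matrix(c(10, 0, 0, 10), 2, 2))
  expect_lt(perfect$p_value, 0.001)
  small <- categorical_test(matrix(c(8, 1, 1, 2), 2, 2))
  expect_equal(small$method, "fisher")  # expected cell < 5 in a 2x2
  expect_error(categorical_test(matrix(c(0, 0, 3, 4), 2, 2)), "margin")
})

test_that("AUC equals the exhaustive pairwise oracle on tiny samples", {
  set.seed(8)
  for (rep in 1:20) {
    n1 <- sample(2:6, 1); n0 <- sample(2:6, 1)
    scores <- round(c(rnorm(n1, 1), rnorm(n0)), 1)  # force some ties
    labels <- c(rep(1, n1), rep(0, n0))
    bf <- mean(outer(scores[labels == 1], scores[labels == 0],
                     function(a, b) (a > b) + 0.5 * (a == b)))
    expect_equal(roc_curve_auc(scores, labels)$auc, bf)
  }
})

test_that("AUC limits and invariances hold", {
  expect_equal(roc_curve_auc(c(1, 2, 9, 10), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_curve_auc(rep(1, 10), rep(0:1, 5))$auc, 0.5)
  set.seed(9)
  s <- rnorm(60); l <- rbinom(60, 1, plogis(s))
  a1 <- roc_curve_auc(s, l)$auc
  expect_equal(roc_curve_auc(exp(3 * s), l)$auc, a1)  # monotone transform
  expect_error(roc_curve_auc(s, rep(1, 60)), "both classes")
})

test_that("DeLong interval covers the point AUC and tightens with n", {
  width <- vapply(c(50, 500), function(n) {
    set.seed(n)
    s <- c(rnorm(n, 1), rnorm(n))
    l <- rep(1:0, each = n)
    r <- roc_curve_auc(s, l)
    expect_gte(r$auc, r$ci[1]); expect_lte(r$auc, r$ci[2])
    r$ci[2] - r$ci[1]
  }, numeric(1))
  expect_lt(width[2], width[1])
})

test_that("Youden cutoff maximises J with specificity tie-break", {
  r <- roc_curve_auc(c(1, 2, 9, 10), c(0, 0, 1, 1))
  yc <- youden_cutoff(r)
  expect_equal(yc$j, 1)
  expect_gt(yc$cutoff, 2); expect_lt(yc$cutoff, 9)
  # antitone relabeling keeps the same optimum J
  r2 <- roc_curve_auc(-c(1, 2, 9, 10), c(1, 1, 0, 0))
  expect_equal(youden_cutoff(r2)$j, yc$j)
})

test_that("binormal specificity at the published cutoff is reproduced", {
  # non-ISR FAI ~ N(-87.2, 7.3^2); specificity at a -82.5 HU cutoff
  spec_closed <- pnorm((-82.5 + 87.2) / 7.3)
  set.seed(10)
  s <- c(rnorm(20000, -78.1, 6.2), rnorm(20000, -87.2, 7.3))
  l <- rep(1:0, each = 20000)
  r <- roc_curve_auc(s, l)
  th <- r$thresholds
  i <- which.min(abs(th$threshold - (-82.5)))
  expect_lt(abs(th$specificity[i] - spec_closed), 0.01)
})

test_that("Pearson estimate, CI and null behave as advertised", {
  x <- 1:10
  expect_equal(pearson_with_ci(x, 2 * x + 1)$r, 1)
  set.seed(11)
  r_hat <- vapply(1:300, function(i) {
    z <- rnorm(52); e <- rnorm(52)
    pearson_with_ci(z, 0.579 * z + sqrt(1 - 0.579^2) * e)$r
  }, numeric(1))
  expect_lt(abs(mean(r_hat) - 0.579), 0.03)
  set.seed(12)
  p_null <- pearson_with_ci(rnorm(1000), rnorm(1000))
  expect_lt(abs(p_null$r), 0.08)
  expect_error(pearson_with_ci(rep(1, 10), rnorm(10)), "constant")
})

test_that("Fisher-z interval attains nominal coverage", {
  set.seed(13)
  rho <- 0.5
  cover <- vapply(1:500, function(i) {
    z <- rnorm(100); e <- rnorm(100)
    y <- rho * z + sqrt(1 - rho^2) * e
    ci <- pearson_with_ci(z, y)$ci
    ci[1] <= rho && rho <= ci[2]
  }, logical(1))
  expect_lt(abs(mean(cover) - 0.95), 0.03)
})

test_that("ICC(2,1) matches the variance-ratio closed form", {
  # identical raters
  set.seed(14)
  a <- rnorm(30)
  expect_equal(icc_absolute(cbind(a, a))$icc, 1)
  # subject SD 7, rater noise SD 0.85 -> ICC = 49 / 49.7225
  expected <- 49 / (49 + 0.85^2)
  est <- vapply(1:200, function(i) {
    subj <- rnorm(117, -80, 7)
    icc_absolute(cbind(subj + rnorm(117, 0, 0.85),
                       subj + rnorm(117, 0, 0.85)))$icc
  }, numeric(1))
  expect_lt(abs(mean(est) - expected), 0.01)
  # pure noise
  noise <- vapply(1:100, function(i)
    icc_absolute(matrix(rnorm(60), 30, 2))$icc, numeric(1))
  expect_lt(abs(mean(noise)), 0.05)
  expect_warning(icc_absolute(matrix(1, 10, 2)), "constant")
})

test_that("noiseless variance components give the exact ICC ratio", {
  subj <- rep(c(-90, -85, -80, -75, -70), each = 2)
  ratings <- cbind(subj, subj + rep(c(-1, 1), 5))
  res <- icc_absolute(ratings)
  # recompute from the same mean squares: exact identity
  manual <- (res$msr - res$mse) /
    (res$msr + res$mse + (2 / res$n) * (res$msc - res$mse))
  expect_equal(res$icc, manual)
})

test_that("LASSO respects penalty bounds along the path", {
  set.seed(15)
  X <- matrix(rnorm(300 * 10), 300, 10)
  colnames(X) <- paste0("v", 1:10)
  y <- rbinom(300, 1, plogis(X[, 1]))
  res <- lasso_select(X, y, seed = 2)
  expect_gte(res$lambda_1se, res$lambda_min)
  fit <- glmnet::glmnet(X, y, family = "binomial",
                        lambda = res$lambda[1] * c(2, 1))
  expect_true(all(as.matrix(fit$beta)[, 1] == 0))  # above lambda_max
  # the 1se model never out-sizes the min-lambda model's in-sample fit
  expect_lte(round(res$auc_1se, 6), round(res$auc_min, 6) + 0.05)
})

test_that("a single strong predictor is selected at lambda.1se", {
  hits <- vapply(1:25, function(s) {
    set.seed(s)
    X <- matrix(rnorm(500 * 21), 500, 21)
    colnames(X) <- c("strong", paste0("noise", 1:20))
    y <- rbinom(500, 1, plogis(1.5 * X[, 1]))
    identical(lasso_select(X, y, seed = s + 1000)$selected_1se, "strong")
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("FAI dominates selection in calibrated cohorts", {
  picks <- vapply(1:15, function(s) {
    coh <- generate_cohort(cohort_config(seed = 300 + s))
    num <- setdiff(names(coh)[vapply(coh, is.numeric, TRUE)],
                   c("id", "isr", "degree_of_isr"))
    res <- suppressWarnings(
      lasso_select(as.matrix(coh[, num]), coh$isr, seed = s))
    "peri_stent_fai_hu" %in% res$selected_1se
  }, logical(1))
  expect_gt(mean(picks), 0.5)
})

test_that("logistic regression recovers known odds ratios", {
  set.seed(16)
  # null: CI covers 1 about 95% of the time
  cover <- vapply(1:200, function(i) {
    d <- data.frame(x = rnorm(500), isr = rbinom(500, 1, 0.4))
    tab <- fit_adjusted_logistic(d, "x", adjusters = character(0))$table
    tab$ci_low <= 1 && 1 <= tab$ci_high
  }, logical(1))
  expect_gt(mean(cover), 0.9)
  # slope ln(2): mean fitted OR near 2
  ors <- vapply(1:200, function(i) {
    x <- rnorm(2000)
    d <- data.frame(x = x, isr = rbinom(2000, 1, plogis(log(2) * x)))
    fit_adjusted_logistic(d, "x", adjusters = character(0))$table$or
  }, numeric(1))
  expect_lt(abs(mean(ors) - 2) / 2, 0.05)
})

test_that("separated data are flagged rather than silently reported", {
  d <- data.frame(x = c(rnorm(20, -5), rnorm(20, 5)),
                  isr = rep(0:1, each = 20))
  expect_warning(res <- fit_adjusted_logistic(d, "x",
                                              adjusters = character(0)),
                 "separation")
  expect_true(res$separation)
})

test_that("subgroup ROC reduces to the global ROC for one stratum", {
  coh <- generate_cohort(cohort_config(seed = 17))
  coh$vessel <- "LAD"
  sub <- subgroup_roc(coh)
  glob <- roc_curve_auc(coh$peri_stent_fai_hu, coh$isr)
  expect_equal(sub$LAD$auc, glob$auc)
  # a single-class stratum is undefined, not an error
  coh2 <- generate_cohort(cohort_config(seed = 18))
  coh2$vessel[coh2$isr == 1] <- "LAD"
  coh2$vessel[coh2$isr == 0][1:10] <- "RCA"
  sub2 <- subgroup_roc(coh2)
  expect_null(sub2$RCA)
})
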
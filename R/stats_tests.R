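#' Two-sample comparison of a continuous variable
#'
#' Standard two-sample t test (Welch by default; Student's pooled-variance
#' variant available) with a two-sided p-value. Degenerate input with zero
#' variance in both groups returns p = 1 when the means are equal (and
#' p = 0 otherwise) by convention.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param method `"welch"` (default) or `"student"`.
#' @return List with `statistic`, `p_value`, `mean_x`, `mean_y`, `method`.
#' @export
two_sample_test <- function(x, y, method = c("welch", "student")) {
  method <- match.arg(method)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 2L || length(y) < 2L)
    stopf("each sample needs n >= 2")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    eq <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(statistic = if (eq) 0 else Inf,
                p_value = if (eq) 1 else 0,
                mean_x = mean(x), mean_y = mean(y), method = method))
  }
  tt <- stats::t.test(x, y, var.equal = (method == "student"))
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       mean_x = mean(x), mean_y = mean(y), method = method)
}

#' Test of association in a 2 x k contingency table
#'
#' Chi-square test without continuity correction; for 2 x 2 tables with any
#' expected cell count below 5 the Fisher exact test is used instead.
#'
#' @param tab 2 x k matrix of nonnegative integer counts.
#' @return List with `statistic` (`NA` for Fisher), `p_value`, `method`.
#' @export
categorical_test <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("contingency table has an empty margin")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5) && all(dim(tab) == 2L)) {
    ft <- stats::fisher.test(tab)
    return(list(statistic = NA_real_, p_value = ft$p.value,
                method = "fisher"))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value,
       method = "chisq")
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Sample correlation, 95% CI via the Fisher z transform with standard
#' error `1 / sqrt(n - 3)`, and a two-sided p-value from the t distribution
#' with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors (n >= 4, nonconstant).
#' @return List with `r`, `ci` (length 2), `p_value`, `n`.
#' @export
pearson_with_ci <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4L) stopf("need n >= 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stopf("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), ci = as.numeric(ct$conf.int),
       p_value = ct$p.value, n = length(x))
}

#' Inter-rater intraclass correlation, ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measures ICC from
#' the mean-squares decomposition of an n x k ratings matrix, with the
#' F-distribution 95% confidence interval.
#'
#' @param ratings n_subjects x k_raters numeric matrix (no missing cells,
#'   n >= 5).
#' @param conf_level Confidence level.
#' @return Object of class `icc_result`: `icc`, `ci`, `model`, mean
#'   squares.
#' @export
icc_absolute <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L || k < 2L) stopf("need >= 5 subjects and >= 2 raters")
  if (any(!is.finite(ratings))) stopf("ratings must be complete")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_r <- k * sum((row_m - grand)^2)
  ss_c <- n * sum((col_m - grand)^2)
  ss_t <- sum((ratings - grand)^2)
  ss_e <- ss_t - ss_r - ss_c
  msr <- ss_r / (n - 1)
  msc <- ss_c / (k - 1)
  mse <- ss_e / ((n - 1) * (k - 1))
  if (msr < 1e-12 && mse < 1e-12) {
    warning("constant ratings: ICC degenerate")
    return(structure(list(icc = NA_real_, ci = c(NA_real_, NA_real_),
                          model = "two-way random, absolute agreement, single measures",
                          msr = msr, msc = msc, mse = mse, n = n, k = k),
                     class = "icc_result"))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  alpha <- 1 - conf_level
  # F-based CI (Shrout & Fleiss / McGraw & Wong, case A-1)
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc = icc, ci = c(lower, upper),
                 model = "two-way random, absolute agreement, single measures",
                 msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("<icc_result> ICC(2,1) = %.3f (95%% CI %.3f-%.3f), %d subjects x %d raters\n",
              x$icc, x$ci[1], x$ci[2], x$n, x$k))
  invisible(x)
}
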
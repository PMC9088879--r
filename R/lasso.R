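#' LASSO feature selection with cross-validated lambda.min and lambda.1se
#'
#' Penalised logistic (binomial-deviance) regression over a 100-point
#' log-spaced lambda grid spanning four decades down from the smallest
#' all-zero-coefficient penalty, with seeded, class-stratified 10-fold
#' cross-validation. Two candidate models are reported: model 1 at
#' `lambda.min` (minimum mean CV deviance) and model 2 at `lambda.1se`
#' (largest lambda whose CV deviance is within one standard error of the
#' minimum). Features are standardised internally; coefficients are
#' returned on the original scale. Each model's in-sample AUC for the
#' outcome is attached.
#'
#' @param x Numeric feature matrix (complete cases; columns named).
#' @param y Binary outcome (0/1).
#' @param folds Number of CV folds.
#' @param seed Seed for the fold assignment.
#' @param nlambda Grid size.
#' @param lambda_min_ratio Ratio of the smallest to the largest grid
#'   lambda.
#' @return Object of class `lasso_selection`: `lambda`, `cvm`, `cvsd`,
#'   `lambda_min`, `lambda_1se`, `coef_min`, `coef_1se`, `selected_min`,
#'   `selected_1se`, `auc_min`, `auc_1se`, `converged`.
#' @export
lasso_select <- function(x, y, folds = 10, seed = 1, nlambda = 100,
                         lambda_min_ratio = 1e-4) {
  x <- as.matrix(x)
  y <- as_binary(y)
  if (anyNA(x) || anyNA(y))
    stopf("missing values: LASSO selection requires complete cases")
  if (min(table(y)) < 2L * folds)
    stopf("need >= 2 cases of each class per fold")
  lambda_max <- glmnet::glmnet(x, y, family = "binomial",
                               standardize = TRUE, nlambda = 3)$lambda[1]
  grid <- exp(seq(log(lambda_max), log(lambda_max * lambda_min_ratio),
                  length.out = nlambda))
  foldid <- integer(length(y))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      foldid[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  converged <- TRUE
  cv <- withCallingHandlers(
    glmnet::cv.glmnet(x, y, family = "binomial", lambda = grid,
                      foldid = foldid, type.measure = "deviance",
                      standardize = TRUE),
    warning = function(w) {
      if (grepl("[Cc]onvergence", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  if (!converged)
    warning("glmnet did not converge over the full lambda grid; ",
            "solutions at the affected small lambdas were truncated",
            call. = FALSE)
  coef_at <- function(s) {
    cf <- as.matrix(stats::coef(cv, s = s))
    stats::setNames(cf[, 1], rownames(cf))
  }
  cmin <- coef_at(cv$lambda.min)
  c1se <- coef_at(cv$lambda.1se)
  sel <- function(cf) names(cf)[cf != 0 & names(cf) != "(Intercept)"]
  insample_auc <- function(cf) {
    lp <- drop(x %*% cf[-1]) + cf[1]
    if (stats::sd(lp) == 0) return(0.5)
    roc_curve_auc(lp, y)$auc
  }
  structure(list(lambda = cv$lambda, cvm = cv$cvm, cvsd = cv$cvsd,
                 lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
                 coef_min = cmin, coef_1se = c1se,
                 selected_min = sel(cmin), selected_1se = sel(c1se),
                 auc_min = insample_auc(cmin), auc_1se = insample_auc(c1se),
                 converged = converged),
            class = "lasso_selection")
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat(sprintf("<lasso_selection> lambda.min %.4f (AUC %.3f), lambda.1se %.4f (AUC %.3f)\n",
              x$lambda_min, x$auc_min, x$lambda_1se, x$auc_1se))
  cat("  model 1 (lambda.min): ",
      paste(x$selected_min, collapse = ", "), "\n", sep = "")
  cat("  model 2 (lambda.1se): ",
      paste(x$selected_1se, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Adjusted logistic regression for ISR predictors
#'
#' Maximum-likelihood logistic regression of the binary ISR outcome on the
#' given predictors, adjusted for covariates (by default age, sex and the
#' clinical risk factors). Odds ratios use Wald 95% intervals
#' `exp(beta +/- 1.96 SE)`. FAI enters per +1 HU, so an OR above 1 means a
#' higher (less negative, more inflamed) FAI raises the odds of
#' restenosis. Quasi-separation is flagged rather than silently reported.
#'
#' @param data Cohort `data.frame` with an `isr` column.
#' @param predictors Character vector of predictor columns.
#' @param adjusters Character vector of adjustment columns (silently
#'   dropped if absent from `data`).
#' @param outcome Outcome column name.
#' @return Object of class `adjusted_logistic`: `table` (data.frame with
#'   `or`, `ci_low`, `ci_high`, `p_value` per predictor), `adjusters`,
#'   `converged`, `separation`, `fit`.
#' @export
fit_adjusted_logistic <- function(data, predictors,
                                  adjusters = c("age", "male",
                                                "hyperlipidemia", "diabetes",
                                                "hypertension", "smoking",
                                                "prior_mi"),
                                  outcome = "isr") {
  adjusters <- intersect(adjusters, names(data))
  vars <- unique(c(predictors, adjusters))
  miss <- setdiff(c(outcome, predictors), names(data))
  if (length(miss))
    stopf("columns missing from data: %s", paste(miss, collapse = ", "))
  fml <- stats::as.formula(paste(outcome, "~",
                                 paste(vars, collapse = " + ")))
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = data, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  separation <- warned || any(abs(cf[, "Estimate"]) > 15)
  if (separation)
    warning("possible separation: odds-ratio confidence intervals may be unbounded")
  rows <- cf[rownames(cf) != "(Intercept)", , drop = FALSE]
  tab <- data.frame(
    predictor = rownames(rows),
    or = exp(rows[, "Estimate"]),
    ci_low = exp(rows[, "Estimate"] - 1.96 * rows[, "Std. Error"]),
    ci_high = exp(rows[, "Estimate"] + 1.96 * rows[, "Std. Error"]),
    p_value = rows[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, adjusters = adjusters,
                 converged = fit$converged, separation = separation,
                 fit = fit),
            class = "adjusted_logistic")
}

#' @export
print.adjusted_logistic <- function(x, ...) {
  cat("<adjusted_logistic> adjusted for:",
      paste(x$adjusters, collapse = ", "), "\n")
  tab <- x$table
  tab$or <- sprintf("%.3f", tab$or)
  tab$ci <- sprintf("%.3f-%.3f", x$table$ci_low, x$table$ci_high)
  print(tab[, c("predictor", "or", "ci", "p_value")], row.names = FALSE)
  invisible(x)
}
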
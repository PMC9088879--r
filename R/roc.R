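#' ROC curve, AUC and DeLong confidence interval
#'
#' AUC by the Mann-Whitney identity (ties receive half credit), oriented so
#' that higher scores indicate the positive class (for peri-stent FAI,
#' higher / less negative attenuation predicts restenosis). The 95% CI uses
#' the DeLong nonparametric variance estimator. Thresholds with their
#' sensitivity/specificity pairs are retained for cutoff selection.
#'
#' @param scores Numeric predictor.
#' @param labels Binary outcome (0/1, logical, or 2-level factor); 1 = the
#'   positive (diseased) class.
#' @param conf_level Confidence level for the DeLong interval.
#' @return Object of class `roc_result`: `auc`, `ci`, `thresholds`
#'   (data.frame: threshold, sensitivity, specificity), `n_pos`, `n_neg`.
#' @export
roc_curve_auc <- function(scores, labels, conf_level = 0.95) {
  labels <- as_binary(labels)
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stopf("both classes must be present to compute a ROC curve")
  r <- pROC::roc(response = labels, predictor = scores,
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- withCallingHandlers(
    as.numeric(pROC::ci.auc(r, conf.level = conf_level,
                            method = "delong"))[c(1, 3)],
    warning = function(w) {
      # the degenerate-curve note for AUC exactly 1 is informational
      if (grepl("AUC == 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  co <- pROC::coords(r, "all",
                     ret = c("threshold", "sensitivity", "specificity"),
                     transpose = FALSE)
  structure(list(auc = as.numeric(pROC::auc(r)), ci = ci,
                 thresholds = as.data.frame(co),
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

as_binary <- function(labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  if (is.logical(labels)) labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L), na.rm = TRUE))
    stopf("labels must be binary (0/1)")
  as.integer(labels)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (95%% CI %.3f-%.3f), %d positive / %d negative\n",
              x$auc, x$ci[1], x$ci[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Youden-index optimal cutoff
#'
#' Chooses the threshold maximising Youden's J = sensitivity +
#' specificity - 1; ties are broken toward the cutoff with the higher
#' specificity.
#'
#' @param roc A `roc_result` from [roc_curve_auc()].
#' @return List with `cutoff`, `sensitivity`, `specificity`, `j`.
#' @export
youden_cutoff <- function(roc) {
  th <- roc$thresholds
  th <- th[is.finite(th$threshold), , drop = FALSE]
  if (nrow(th) == 0L) stopf("degenerate ROC: no finite thresholds")
  j <- th$sensitivity + th$specificity - 1
  best <- which(j > max(j) - 1e-12)
  best <- best[which.max(th$specificity[best])]
  list(cutoff = th$threshold[best],
       sensitivity = th$sensitivity[best],
       specificity = th$specificity[best],
       j = j[best])
}

#' Per-stratum ROC analysis
#'
#' Applies [roc_curve_auc()] within each level of a grouping column
#' (typically the stented vessel). Strata containing a single outcome class
#' are reported as undefined (`NULL` entries) rather than errors.
#'
#' @param data Cohort `data.frame`.
#' @param score_col,label_col,key Column names for the predictor, the
#'   binary outcome and the stratifier.
#' @return Named list of `roc_result` (or `NULL` where undefined).
#' @export
subgroup_roc <- function(data, score_col = "peri_stent_fai_hu",
                         label_col = "isr", key = "vessel") {
  out <- list()
  for (lev in unique(as.character(data[[key]]))) {
    sub <- data[data[[key]] == lev, ]
    lab <- as_binary(sub[[label_col]])
    if (length(unique(lab)) < 2L) {
      out[[lev]] <- NULL
      out[lev] <- list(NULL)
    } else {
      out[[lev]] <- roc_curve_auc(sub[[score_col]], lab)
    }
  }
  out
}
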
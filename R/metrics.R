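## Classification metrics: accuracy, support-weighted and macro
## precision/recall/F1, confusion matrix, and one-vs-rest ROC curves.
## Support-weighted recall equals overall accuracy algebraically
## (sum_c support_c/N * TP_c/support_c = sum_c TP_c / N), which is the
## signature visible in the reference result tables where the recall column
## always equals the accuracy column.

#' Compute a metrics report
#'
#' @param truth Character vector of true labels.
#' @param predicted Character vector of predicted labels (same length).
#' @param classes Ordered class vocabulary.
#' @param probs Optional (N, K) matrix of class probabilities (columns in
#'   `classes` order) used for the one-vs-rest ROC curves.
#' @return A [MetricsReport-class]; all rates in percent. Classes absent
#'   from `truth` get NA per-class metrics and are excluded from the
#'   weighted and macro averages.
#' @export
computeMetrics <- function(truth, predicted, classes, probs = NULL) {
  wfAssert(length(truth) == length(predicted) && length(truth) > 0,
           "need equally long, non-empty truth and prediction vectors")
  tf <- factor(truth, levels = classes)
  pf <- factor(predicted, levels = classes)
  conf <- unclass(table(truth = tf, predicted = pf))
  n <- length(truth)
  acc <- 100 * sum(diag(conf)) / n
  support <- rowSums(conf)
  tp <- diag(conf)
  predN <- colSums(conf)
  prec <- ifelse(support == 0, NA_real_,
                 ifelse(predN == 0, 0, tp / pmax(predN, 1)))
  rec <- ifelse(support == 0, NA_real_, tp / pmax(support, 1))
  f1 <- ifelse(is.na(prec) | is.na(rec), NA_real_,
               ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec)))
  perClass <- data.frame(class = classes, precision = 100 * prec,
                         recall = 100 * rec, f1 = 100 * f1,
                         support = as.integer(support), row.names = NULL)
  present <- support > 0
  wAvg <- function(v) sum(v[present] * support[present]) / sum(support[present])
  weighted <- c(precision = 100 * wAvg(prec), recall = 100 * wAvg(rec),
                f1 = 100 * wAvg(f1))
  macro <- c(precision = 100 * mean(prec[present]),
             recall = 100 * mean(rec[present]),
             f1 = 100 * mean(f1[present]))
  roc <- list()
  if (!is.null(probs)) {
    colnames(probs) <- classes
    for (cl in classes[present]) {
      pos <- truth == cl
      if (all(pos) || !any(pos)) next
      r <- tryCatch(
        pROC::roc(response = factor(pos, levels = c(FALSE, TRUE)),
                  predictor = probs[, cl], quiet = TRUE, direction = "<"),
        error = function(e) NULL)
      if (is.null(r)) next
      df <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
      df <- df[order(df$fpr, df$tpr), , drop = FALSE]
      attr(df, "auc") <- as.numeric(r$auc)
      roc[[cl]] <- df
    }
  }
  methods::new("MetricsReport", accuracy = acc, weighted = weighted,
               macro = macro, perClass = perClass, confusion = conf,
               roc = roc, classes = classes)
}
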
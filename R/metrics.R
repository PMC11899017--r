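# Multiclass evaluation: confusion matrix, one-vs-rest metrics, ROC-AUC,
# Cohen's kappa, and the assembled evaluation report.

#' Confusion matrix
#'
#' Entry `(i, j)` counts samples whose true class is `i` and predicted
#' class is `j` (rows = truth, columns = prediction).
#'
#' @param y_true,y_pred Integer labels in `1..n_classes`.
#' @param n_classes Number of classes K.
#' @return `K x K` integer matrix; `sum(cm) == length(y_true)`.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred differ in length", call. = FALSE)
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (any(y_true < 1 | y_true > n_classes | y_pred < 1 | y_pred > n_classes))
    stop("labels out of range 1..", n_classes, call. = FALSE)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(y_true))
    cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1L
  cm
}

#' One-vs-rest metrics from a confusion matrix
#'
#' For each class k (one-vs-rest): precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)`, F1 `2TP/(2TP+FP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/N`. Macro values are unweighted means; overall accuracy is
#' `trace/N`. A zero denominator yields 0 with the class flagged in
#' `degenerate`.
#'
#' @param cm Square confusion matrix (rows = truth).
#' @return List: `per_class` data frame, `macro` named vector,
#'   `overall_accuracy`, `degenerate` (class indices with a zero
#'   denominator).
#' @export
metrics_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  stopifnot(nrow(cm) == ncol(cm), all(cm >= 0))
  n <- sum(cm)
  k <- nrow(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- n - tp - fp - fn
  div <- function(num, den) {
    den <- rep_len(den, length(num))
    ifelse(den > 0, num / den, 0)
  }
  per <- data.frame(
    class = seq_len(k), tp = tp, fp = fp, fn = fn, tn = tn,
    precision = div(tp, tp + fp),
    recall = div(tp, tp + fn),
    f1 = div(2 * tp, 2 * tp + fp + fn),
    specificity = div(tn, tn + fp),
    accuracy = div(tp + tn, n))
  degenerate <- which(tp + fp == 0 | tp + fn == 0 | tn + fp == 0)
  macro <- c(precision = mean(per$precision), recall = mean(per$recall),
             f1 = mean(per$f1), specificity = mean(per$specificity),
             accuracy = mean(per$accuracy))
  list(per_class = per, macro = macro,
       overall_accuracy = if (n > 0) sum(tp) / n else 0,
       degenerate = degenerate)
}

#' One-vs-rest ROC-AUC from probability scores
#'
#' Per class, the AUC is computed with the midrank (Mann-Whitney) statistic,
#' which equals the trapezoidal integral of the ROC curve with ties handled
#' by midranks. A class absent from `labels` has no defined AUC and is
#' reported as `NA`.
#'
#' @param scores `N x K` matrix of class probabilities (rows ~ sum to 1).
#' @param labels Integer labels in `1..K`.
#' @return List: `per_class` (numeric, `NA` where undefined), `macro`
#'   (mean over defined classes).
#' @export
roc_auc_ovr <- function(scores, labels) {
  scores <- as.matrix(scores)
  k <- ncol(scores)
  labels <- as.integer(labels)
  if (any(labels < 1 | labels > k))
    stop("labels out of range 1..", k, call. = FALSE)
  auc <- vapply(seq_len(k), function(cls) {
    pos <- labels == cls
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0 || n0 == 0) return(NA_real_)
    r <- rank(scores[, cls])           # midranks for ties
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  list(per_class = auc, macro = mean(auc, na.rm = TRUE))
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (po - pe) / (1 - pe)` with observed agreement `po = trace/N`
#' and chance agreement `pe = sum(row_i * col_i) / N^2`. Equals 1 exactly
#' when the off-diagonal is empty; defined as 0 (with a warning) when
#' `pe = 1`.
#'
#' @param cm Square confusion matrix.
#' @return Scalar kappa.
#' @export
cohen_kappa <- function(cm) {
  cm <- as.matrix(cm)
  n <- sum(cm)
  stopifnot(n > 0)
  po <- sum(diag(cm)) / n
  pe <- sum(rowSums(cm) * colSums(cm)) / n^2
  if (pe >= 1) {
    if (po >= 1) return(1)
    warning("chance agreement pe = 1; kappa defined as 0", call. = FALSE)
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' Full evaluation report for a trained model
#'
#' Assembles the confusion matrix, per-class and macro one-vs-rest metrics,
#' overall accuracy, per-class ROC-AUC, Cohen's kappa, and the loss
#' `L = 1 - overall accuracy` used as the search fitness.
#'
#' @param model A trained `nas_model`.
#' @param test An `image_dataset`.
#' @return Object of class `eval_report`.
#' @export
evaluate_model <- function(model, test) {
  probs <- predict(model, test)
  y_pred <- max.col(probs, ties.method = "first")
  k <- length(test$class_names)
  cm <- confusion_matrix(test$labels, y_pred, k)
  mets <- metrics_from_confusion(cm)
  auc <- roc_auc_ovr(probs, test$labels)
  per <- mets$per_class
  per$class <- test$class_names
  per$roc_auc <- auc$per_class
  structure(list(confusion_matrix = cm, per_class = per,
                 macro = mets$macro,
                 overall_accuracy = mets$overall_accuracy,
                 macro_auc = auc$macro, kappa = cohen_kappa(cm),
                 loss = 1 - mets$overall_accuracy,
                 n_test = sum(cm), class_names = test$class_names,
                 scores = probs, y_true = test$labels),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report> n = %d | accuracy %.4f | macro F1 %.4f | macro AUC %.4f | kappa %.4f | loss %.4f\n",
    x$n_test, x$overall_accuracy, x$macro["f1"], x$macro_auc, x$kappa,
    x$loss))
  print(x$per_class[, c("class", "precision", "recall", "f1", "specificity",
                        "accuracy", "roc_auc")], row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report's artifacts
#'
#' Writes `report.json` (metrics), `confusion.csv`, and one ROC point CSV
#' per class under `dir`.
#'
#' @param report An `eval_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list(overall_accuracy = report$overall_accuracy,
              macro = as.list(report$macro), macro_auc = report$macro_auc,
              kappa = report$kappa, loss = report$loss,
              n_test = report$n_test,
              per_class = report$per_class)
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  cm <- as.data.frame(report$confusion_matrix)
  names(cm) <- report$class_names
  cm <- cbind(true_class = report$class_names, cm)
  write.csv(cm, file.path(dir, "confusion.csv"), row.names = FALSE)
  for (k in seq_along(report$class_names)) {
    sc <- report$scores[, k]
    pos <- report$y_true == k
    ord <- order(sc, decreasing = TRUE)
    tpr <- cumsum(pos[ord]) / max(sum(pos), 1)
    fpr <- cumsum(!pos[ord]) / max(sum(!pos), 1)
    write.csv(data.frame(threshold = sc[ord], fpr = fpr, tpr = tpr),
              file.path(dir, sprintf("roc_%s.csv", report$class_names[k])),
              row.names = FALSE)
  }
  invisible(dir)
}
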
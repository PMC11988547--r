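## Evaluation metrics: accuracy / precision / recall / F1 from the
## confusion matrix (macro one-vs-rest for multiclass tasks), ROC curves
## and trapezoidal AUC.

#' Classification metrics from confusion counts
#'
#' Direct evaluation of the four standard formulas for a binary confusion:
#' accuracy (TP+TN)/(TP+TN+FP+FN), precision TP/(TP+FP), recall
#' TP/(TP+FN), and the F1 harmonic mean.
#'
#' @param tp,fp,tn,fn confusion counts.
#' @return Named list: accuracy, precision, recall, f1.
#' @export
#' @examples
#' metricsFromCounts(tp = 50, fp = 5, tn = 40, fn = 5)
metricsFromCounts <- function(tp, fp, tn, fn) {
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(accuracy = (tp + tn) / (tp + tn + fp + fn),
       precision = precision, recall = recall, f1 = f1)
}

#' Classification metrics for a prediction vector
#'
#' Accuracy is global (trace of the confusion matrix over the total). For
#' two-class tasks precision/recall/F1 are computed per class and
#' macro-averaged, exactly as in the multiclass case, so that the 2-class
#' subtype task and the 3-class survival task are scored under one scheme.
#' A class absent from `yTrue` has undefined per-class metrics; it is
#' excluded from the macro mean with a message.
#'
#' @param yTrue,yPred equal-length label vectors.
#' @param classes class set (defaults to the classes seen in either
#'   vector, sorted).
#' @return List: accuracy, precision, recall, f1 (macro), perClass
#'   data.frame, confusion matrix (rows = truth).
#' @export
classificationMetrics <- function(yTrue, yPred, classes = NULL) {
  if (length(yTrue) != length(yPred)) validationError("length mismatch")
  if (is.null(classes)) classes <- sort(unique(c(yTrue, yPred)))
  yT <- factor(yTrue, levels = classes)
  yP <- factor(yPred, levels = classes)
  conf <- table(truth = yT, predicted = yP)
  perClass <- lapply(classes, function(cl) {
    tp <- sum(yT == cl & yP == cl)
    fp <- sum(yT != cl & yP == cl)
    fn <- sum(yT == cl & yP != cl)
    support <- sum(yT == cl)
    if (support == 0L) {
      data.frame(class = cl, precision = NA_real_, recall = NA_real_,
                 f1 = NA_real_, support = 0L)
    } else {
      m <- metricsFromCounts(tp, fp, length(yT) - tp - fp - fn, fn)
      prec <- if (is.na(m$precision)) 0 else m$precision
      rec <- m$recall
      f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
      data.frame(class = cl, precision = prec, recall = rec, f1 = f1,
                 support = support)
    }
  })
  perClass <- do.call(rbind, perClass)
  absent <- perClass$support == 0L
  if (any(absent)) {
    message("class(es) absent from yTrue excluded from macro mean: ",
            paste(perClass$class[absent], collapse = ", "))
  }
  use <- !absent
  list(accuracy = sum(diag(conf)) / length(yT),
       precision = mean(perClass$precision[use]),
       recall = mean(perClass$recall[use]),
       f1 = mean(perClass$f1[use]),
       perClass = perClass,
       confusion = conf)
}

#' ROC curve and AUC
#'
#' Binary: `scores` is the probability of the positive class (the larger
#' label); the ROC is swept over all score thresholds and the AUC computed
#' by trapezoidal integration, which equals the rank statistic (the
#' probability that a random positive outscores a random negative, ties
#' counted 1/2). Multiclass: `scores` is a matrix with one column per
#' class and the AUC is the macro mean of the one-vs-rest AUCs.
#'
#' @param yTrue label vector.
#' @param scores numeric vector (binary) or matrix with named columns
#'   (multiclass).
#' @return List: `auc`, and `roc` (data.frame fpr/tpr, binary case) or
#'   `perClass` (named numeric, multiclass case).
#' @export
#' @examples
#' rocAuc(c(0, 0, 1, 1), c(.1, .4, .35, .8))
rocAuc <- function(yTrue, scores) {
  classes <- sort(unique(yTrue))
  if (length(classes) < 2L) {
    degenerateError("AUC undefined with a single observed class")
  }
  if (is.matrix(scores)) {
    if (length(classes) == 2L && ncol(scores) >= 2L) {
      sc <- scores[, as.character(classes[2L])]
      return(rocAuc(yTrue, sc))
    }
    per <- vapply(as.character(classes), function(cl) {
      rocAuc(as.integer(yTrue == cl), scores[, cl])$auc
    }, numeric(1))
    return(list(auc = mean(per), perClass = per))
  }
  pos <- yTrue == classes[2L]
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(auc = auc, roc = data.frame(fpr = fpr, tpr = tpr))
}
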
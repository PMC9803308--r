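#' Confusion matrix over the five delineation classes
#'
#' Rows are true classes, columns predicted, both in the canonical order
#' P, QRS, T, ISO, PAD (see [ecg_classes()]).
#'
#' @param true_labels,predicted_labels Equal-length character vectors.
#' @param classes Class order; defaults to [ecg_classes()].
#' @return Integer matrix of class `confusion_matrix`.
#' @export
confusion <- function(true_labels, predicted_labels, classes = ecg_classes()) {
  if (length(true_labels) != length(predicted_labels))
    stop("confusion: label vectors differ in length")
  cm <- table(factor(true_labels, levels = classes),
              factor(predicted_labels, levels = classes))
  m <- matrix(as.integer(cm), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  class(m) <- c("confusion_matrix", class(m))
  m
}

#' Per-class one-vs-rest metrics
#'
#' For each class c, with one-vs-rest TP / FP / FN / TN counts:
#' accuracy `(TP+TN)/total`, sensitivity `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, precision `TP/(TP+FP)` and F1 (harmonic mean of precision
#' and sensitivity). A metric with a zero denominator is reported as `NaN`
#' (a distinguished undefined value), never silently zero. The `Average` row
#' is the unweighted mean over all classes (including zero-padding).
#'
#' @param cm A [confusion()] matrix.
#' @return Data frame, one row per class plus an `Average` row; columns
#'   `class`, `accuracy`, `sensitivity`, `specificity`, `precision`, `f1`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- sum(cm)
  classes <- rownames(cm)
  safe_div <- function(a, b) if (b == 0) NaN else a / b
  rows <- lapply(seq_along(classes), function(k) {
    tp <- cm[k, k]
    fn <- sum(cm[k, ]) - tp
    fp <- sum(cm[, k]) - tp
    tn <- total - tp - fn - fp
    sens <- safe_div(tp, tp + fn)
    prec <- safe_div(tp, tp + fp)
    f1 <- if (is.nan(sens) || is.nan(prec) || (sens + prec) == 0) NaN
          else 2 * sens * prec / (sens + prec)
    data.frame(class = classes[k],
               accuracy = safe_div(tp + tn, total),
               sensitivity = sens,
               specificity = safe_div(tn, tn + fp),
               precision = prec, f1 = f1)
  })
  out <- do.call(rbind, rows)
  avg <- data.frame(class = "Average",
                    accuracy = mean(out$accuracy),
                    sensitivity = mean(out$sensitivity),
                    specificity = mean(out$specificity),
                    precision = mean(out$precision), f1 = mean(out$f1))
  rbind(out, avg)
}

# one-vs-rest ROC points by threshold sweep; returns fpr/tpr sorted ascending
.roc_points <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]; score <- score[ord]
  # evaluate at the last index of each tied-score group
  last_of_group <- which(!duplicated(score, fromLast = TRUE))
  tp <- cumsum(truth)[last_of_group]
  fp <- last_of_group - tp
  P <- sum(truth); N <- length(truth) - P
  data.frame(fpr = c(0, fp / N), tpr = c(0, tp / P))
}

#' One-vs-rest ROC and precision-recall curves with areas
#'
#' Sweeps every distinct score threshold per class. ROC area uses the
#' trapezoidal rule; PR area uses step-wise interpolation (precision held at
#' its value while recall advances), the convention under which a random
#' classifier scores the class prevalence. A class absent from the truth
#' gets `NA` areas and empty curves. Micro (all classes pooled one-vs-rest)
#' and macro (mean over defined classes) average areas are also returned.
#'
#' @param true_labels Character vector of ground-truth classes, length n.
#' @param probabilities n x K matrix of class probabilities (rows sum to 1);
#'   column names give the class order, defaulting to [ecg_classes()].
#' @return List with `per_class` (per class: `roc` points, `pr` points,
#'   `auc_roc`, `auc_pr`), `macro` and `micro` (`auc_roc`, `auc_pr` each).
#' @export
roc_pr_curves <- function(true_labels, probabilities) {
  if (is.null(colnames(probabilities)))
    colnames(probabilities) <- ecg_classes()[seq_len(ncol(probabilities))]
  if (any(abs(rowSums(probabilities) - 1) > 1e-6))
    stop("roc_pr_curves: probability rows must sum to 1")
  classes <- colnames(probabilities)
  per <- lapply(classes, function(cl) {
    truth <- as.integer(true_labels == cl)
    if (sum(truth) == 0 || sum(truth) == length(truth))
      return(list(roc = NULL, pr = NULL, auc_roc = NA_real_,
                  auc_pr = NA_real_))
    sc <- probabilities[, cl]
    roc <- .roc_points(truth, sc)
    auc_roc <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                      utils::tail(roc$tpr, -1)) / 2)
    pr <- .pr_points(truth, sc)
    auc_pr <- sum(diff(c(0, pr$recall)) * pr$precision)
    list(roc = roc, pr = pr, auc_roc = auc_roc, auc_pr = auc_pr)
  })
  names(per) <- classes
  aucs_roc <- vapply(per, function(p) p$auc_roc, numeric(1))
  aucs_pr <- vapply(per, function(p) p$auc_pr, numeric(1))
  # micro: pool all one-vs-rest decisions
  truth_all <- as.integer(unlist(lapply(classes, function(cl) true_labels == cl)))
  score_all <- as.numeric(probabilities)
  micro_roc <- .roc_points(truth_all, score_all)
  micro_auc_roc <- sum(diff(micro_roc$fpr) *
                         (utils::head(micro_roc$tpr, -1) +
                            utils::tail(micro_roc$tpr, -1)) / 2)
  micro_pr <- .pr_points(truth_all, score_all)
  micro_auc_pr <- sum(diff(c(0, micro_pr$recall)) * micro_pr$precision)
  list(per_class = per,
       macro = list(auc_roc = mean(aucs_roc, na.rm = TRUE),
                    auc_pr = mean(aucs_pr, na.rm = TRUE)),
       micro = list(auc_roc = micro_auc_roc, auc_pr = micro_auc_pr))
}

.pr_points <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  truth <- truth[ord]; score <- score[ord]
  grp_last <- which(!duplicated(score, fromLast = TRUE))
  tp <- cumsum(truth)[grp_last]
  fp <- grp_last - tp
  P <- sum(truth)
  data.frame(recall = tp / P, precision = tp / (tp + fp))
}

#' Full delineation evaluation report
#'
#' Confusion matrix, per-class metrics and ROC / PR areas for a model over
#' labeled frames.
#'
#' @param model A `delineator_model`.
#' @param frames Labeled held-out frames.
#' @return List `confusion`, `metrics`, `curves`.
#' @export
evaluate_delineator <- function(model, frames) {
  pred <- delineator_predictions(model, frames)
  cm <- confusion(pred$truth, pred$labels)
  list(confusion = cm, metrics = per_class_metrics(cm),
       curves = roc_pr_curves(pred$truth, pred$probabilities))
}
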
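#' Confusion matrix (rows = predicted, columns = actual)
#'
#' @param y_true,y_pred integer labels in 1..4 (untracked/transition frames
#'   must be excluded beforehand).
#' @param n_classes number of classes.
#' @return n_classes x n_classes integer matrix; cell \code{[p, a]} counts
#'   frames predicted \code{p} whose actual class is \code{a}.
#' @export
confusion_matrix <- function(y_true, y_pred, n_classes = 4L) {
  if (length(y_true) == 0L) stop("empty input: no frames to score")
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred differ in length")
  lv <- seq_len(n_classes)
  if (any(!(y_true %in% lv)) || any(!(y_pred %in% lv)))
    stop("labels must lie in 1..", n_classes)
  cm <- table(predicted = factor(y_pred, levels = lv),
              actual = factor(y_true, levels = lv))
  matrix(as.integer(cm), n_classes, n_classes,
         dimnames = list(predicted = lv, actual = lv))
}

#' One-vs-rest metrics for a single class
#'
#' Reduces the multi-class confusion matrix to a binary problem for the
#' given class: TP is the diagonal cell, FP the rest of the predicted row,
#' FN the rest of the actual column, TN everything else. Then
#' accuracy = (TP+TN)/total, sensitivity (recall) = TP/(TP+FN),
#' specificity = TN/(TN+FP), precision = TP/(TP+FP) and
#' F-score = 2 x precision x recall / (precision + recall). Any metric whose
#' denominator is zero is reported as 0 (and flagged with a message).
#'
#' @param cm confusion matrix from \code{\link{confusion_matrix}}.
#' @param class class index.
#' @return named list with the four counts and the five metrics.
#' @export
class_metrics <- function(cm, class) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  tp <- cm[class, class]
  fp <- sum(cm[class, ]) - tp
  fn <- sum(cm[, class]) - tp
  tn <- total - tp - fp - fn
  safe <- function(num, den, what) {
    if (den == 0) {
      message("class ", class, ": ", what,
              " has zero denominator; reported as 0")
      return(0)
    }
    num / den
  }
  sens <- safe(tp, tp + fn, "sensitivity")
  prec <- safe(tp, tp + fp, "precision")
  list(TP = tp, TN = tn, FP = fp, FN = fn,
       accuracy = (tp + tn) / total,
       sensitivity = sens,
       specificity = safe(tn, tn + fp, "specificity"),
       precision = prec,
       f_score = safe(2 * prec * sens, prec + sens, "F-score"))
}

#' Overall fraction of correctly classified frames
#'
#' \code{trace(cm) / total}. The companion
#' \code{\link{mean_class_accuracy}} averages the four one-vs-rest class
#' accuracies instead; both readings of a "total" accuracy are reported by
#' \code{\link{summarize_simulations}}.
#'
#' @param cm confusion matrix.
#' @return fraction in [0, 1].
#' @export
total_accuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' @rdname total_accuracy
#' @export
mean_class_accuracy <- function(cm) {
  mean(vapply(seq_len(nrow(cm)),
              function(cl) class_metrics(cm, cl)$accuracy, 0))
}

#' Evaluation report for one simulation
#'
#' Bundles the confusion matrix, per-class one-vs-rest metrics, both total
#' accuracy readings and (when probabilities are supplied) per-class ROC
#' curves with AUC.
#'
#' @param y_true,y_pred integer labels 1..4.
#' @param probs optional n x 4 matrix of class probabilities.
#' @return object of class \code{eval_report}.
#' @export
eval_report <- function(y_true, y_pred, probs = NULL) {
  cm <- confusion_matrix(y_true, y_pred)
  per_class <- lapply(seq_len(4L), function(cl) class_metrics(cm, cl))
  roc <- NULL
  if (!is.null(probs)) {
    roc <- lapply(seq_len(4L), function(cl) {
      if (length(unique(y_true == cl)) < 2L) return(NULL)
      roc_curve(probs[, cl], y_true == cl)
    })
  }
  structure(list(confusion = cm, per_class = per_class,
                 total_accuracy = total_accuracy(cm),
                 mean_class_accuracy = mean_class_accuracy(cm),
                 roc = roc),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: %d frames, total accuracy %.4f\n",
              sum(x$confusion), x$total_accuracy))
  print(x$confusion)
  invisible(x)
}

#' Summarize repeated simulations
#'
#' Mean and SD of every metric over the simulation reports, plus the
#' element-wise mean confusion matrix (cells are mean frame counts over the
#' simulations).
#'
#' @param reports list of \code{\link{eval_report}}s (or a
#'   \code{simulation_set}).
#' @return list: \code{metrics} (data.frame class x metric with mean and
#'   sd), \code{total_accuracy} (mean, sd), \code{mean_class_accuracy}
#'   (mean, sd), \code{mean_confusion}, \code{n_simulations}.
#' @export
summarize_simulations <- function(reports) {
  if (inherits(reports, "simulation_set")) reports <- reports$reports
  if (length(reports) < 1L) stop("need at least one report")
  metric_names <- c("accuracy", "sensitivity", "specificity", "precision",
                    "f_score")
  rows <- list()
  for (cl in 1:4) {
    for (mn in metric_names) {
      vals <- vapply(reports, function(r) r$per_class[[cl]][[mn]], 0)
      rows[[length(rows) + 1L]] <- data.frame(
        class = cl, metric = mn, mean = mean(vals),
        sd = if (length(vals) > 1L) stats::sd(vals) else 0)
    }
  }
  tot <- vapply(reports, function(r) r$total_accuracy, 0)
  mca <- vapply(reports, function(r) r$mean_class_accuracy, 0)
  cms <- lapply(reports, function(r) r$confusion)
  list(metrics = do.call(rbind, rows),
       total_accuracy = c(mean = mean(tot),
                          sd = if (length(tot) > 1L) stats::sd(tot) else 0),
       mean_class_accuracy = c(mean = mean(mca),
                               sd = if (length(mca) > 1L) stats::sd(mca) else 0),
       mean_confusion = Reduce("+", cms) / length(cms),
       n_simulations = length(reports))
}

#' One-vs-rest ROC curve by exact threshold sweep
#'
#' Sweeps every distinct score as a classification threshold (predict
#' positive when score >= threshold), plus the two degenerate endpoints, and
#' plots the true positive rate (sensitivity) against the false positive
#' rate (1 - specificity). AUC by the trapezoid rule.
#'
#' @param scores numeric scores (e.g. the class's membership probability).
#' @param positive logical (or 0/1) ground truth for the class.
#' @return object of class \code{roc_curve}: \code{fpr}, \code{tpr}
#'   (non-decreasing, from (0,0) to (1,1)) and \code{auc} in [0, 1].
#' @export
roc_curve <- function(scores, positive) {
  positive <- as.logical(positive)
  stopifnot(length(scores) == length(positive), all(is.finite(scores)))
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC undefined: need at least one positive and one negative")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- positive[o]
  tp <- cumsum(p); fp <- cumsum(!p)
  # keep the last index of each tied-score block: all-or-none at a threshold
  last <- c(s[-length(s)] != s[-1], TRUE)
  tpr <- c(0, tp[last] / n_pos)
  fpr <- c(0, fp[last] / n_neg)
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = fpr, tpr = tpr, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: %d points, AUC %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Average ROC curves over simulations
#'
#' Interpolates every curve's TPR onto a common FPR grid and averages
#' pointwise, giving the mean true positive rate for each value of the false
#' positive rate. At grid points where a curve is vertical the largest TPR
#' is used.
#'
#' @param curves list of \code{\link{roc_curve}}s.
#' @param grid FPR grid; default \code{seq(0, 1, by = 0.001)}.
#' @return a \code{roc_curve} on the grid (AUC by trapezoid on the grid).
#' @export
mean_roc <- function(curves, grid = seq(0, 1, by = 0.001)) {
  curves <- Filter(Negate(is.null), curves)
  if (length(curves) == 0L) stop("no curves to average")
  tprs <- vapply(curves, function(cv) {
    ct <- cummax(cv$tpr)
    idx <- pmax(findInterval(grid + 1e-15, cv$fpr), 1L)
    ct[idx]
  }, numeric(length(grid)))
  tpr <- rowMeans(as.matrix(tprs))
  auc <- sum(diff(grid) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(fpr = grid, tpr = tpr, auc = auc), class = "roc_curve")
}

#' Shapiro-Wilk normality check for repeated-simulation metrics
#'
#' Used on the per-simulation metric values (typically 50 of them) before
#' reporting their mean and standard deviation.
#'
#' @param values numeric vector, 3 <= n <= 5000, not all equal.
#' @return list with \code{W} and \code{p_value}.
#' @export
normality_test <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L || length(values) > 5000L)
    stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (diff(range(values)) == 0) stop("constant input: normality undefined")
  ht <- stats::shapiro.test(values)
  list(W = unname(ht$statistic), p_value = unname(ht$p.value))
}
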
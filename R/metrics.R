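# Classifier evaluation metrics, all on the percent scale.
# "Classifier k" (k = 1, 2, 3) refers to the k-th tree node, whose positive
# class is phase k; the upper buffer has no node of its own (it is the
# residual class), so per-node tables have three columns.

#' Overall recognition rate
#'
#' `100 * sum(per-phase correct counts) / n_total`.
#'
#' @param per_phase_correct four correct-classification counts
#' @param n_total total number of test samples
#' @return recognition rate in percent
#' @export
recognition_rate <- function(per_phase_correct, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (any(per_phase_correct < 0) || sum(per_phase_correct) > n_total)
    stop("counts must be >= 0 and sum to at most n_total")
  100 * sum(per_phase_correct) / n_total
}

#' Precision and recall from binary confusion counts
#'
#' `precision = 100 TP / (TP + FP)`, `recall = 100 TP / (TP + FN)`; an
#' empty denominator yields 0 with a warning.
#'
#' @param tp,fp,fn true-positive, false-positive, false-negative counts
#' @return named numeric `c(precision =, recall =)`, percent
#' @export
precision_recall <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("confusion counts must be >= 0")
  if (tp + fp + fn == 0) stop("all-zero confusion")
  prec <- if (tp + fp == 0) { warning("no positive predictions; precision set to 0"); 0 }
          else 100 * tp / (tp + fp)
  rec <- if (tp + fn == 0) { warning("no positive truths; recall set to 0"); 0 }
         else 100 * tp / (tp + fn)
  c(precision = prec, recall = rec)
}

#' F1 score (harmonic mean of precision and recall)
#'
#' @param precision,recall percentages in [0, 100]
#' @return F1 in percent; 0 with a warning when both inputs are 0
#' @export
f1_score <- function(precision, recall) {
  if (any(c(precision, recall) < 0 | c(precision, recall) > 100))
    stop("precision and recall must be in [0, 100]")
  if (precision + recall == 0) {
    warning("precision and recall both 0; F1 set to 0")
    return(0)
  }
  2 * precision * recall / (precision + recall)
}

#' G index (geometric mean of precision and recall)
#'
#' `sqrt(P * R)`; always at least the F1 harmonic mean, with equality iff
#' P = R.
#'
#' @param precision,recall percentages in [0, 100]
#' @return G index in percent
#' @export
g_index <- function(precision, recall) {
  if (any(c(precision, recall) < 0 | c(precision, recall) > 100))
    stop("precision and recall must be in [0, 100]")
  sqrt(precision * recall)
}

#' Average and population standard deviation of the three node precisions
#'
#' The spread column of the precision table uses the population convention
#' (divisor 3, not 2).
#'
#' @param precisions exactly three precision percentages
#' @return named numeric `c(average =, sd =)`
#' @export
precision_summary <- function(precisions) {
  if (length(precisions) != 3) stop("exactly three precisions expected")
  m <- mean(precisions)
  c(average = m, sd = sqrt(mean((precisions - m)^2)))
}

#' Full metrics report from true and predicted phases
#'
#' Per-phase correct counts and overall recognition rate, plus one-vs-rest
#' precision, recall, F1 and G index for the three tree nodes (positive
#' phases 1-3) and the precision average / population standard deviation.
#'
#' @param y_true,y_pred integer phase labels in {1, 2, 3, 4}
#' @return object of class `metrics_report`
#' @export
metrics_report <- function(y_true, y_pred) {
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  if (length(y_true) != length(y_pred)) stop("label vectors differ in length")
  if (!all(c(y_true, y_pred) %in% 1:4)) stop("labels must be in {1, 2, 3, 4}")
  correct <- vapply(1:4, function(k) sum(y_true == k & y_pred == k), integer(1))
  node <- t(vapply(1:3, function(k) {
    tp <- sum(y_true == k & y_pred == k)
    pr <- precision_recall(tp, sum(y_pred == k) - tp, sum(y_true == k) - tp)
    c(pr, f1 = f1_score(pr[["precision"]], pr[["recall"]]),
      g = g_index(pr[["precision"]], pr[["recall"]]))
  }, numeric(4)))
  rownames(node) <- paste0("classifier", 1:3)
  structure(list(per_phase_correct = correct,
                 n_total = length(y_true),
                 recognition_rate = recognition_rate(correct, length(y_true)),
                 node = node,
                 precision_summary = precision_summary(node[, "precision"])),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Recognition rate: %.2f%% (%d/%d)\n",
              x$recognition_rate, sum(x$per_phase_correct), x$n_total))
  cat("Per-phase correct:",
      paste(c("pedaling", "lower buffer", "relaxation", "upper buffer"),
            x$per_phase_correct, sep = "=", collapse = ", "), "\n")
  print(round_half_up(x$node, 2))
  cat(sprintf("Precision average %.2f%%, population sd %.2f%%\n",
              x$precision_summary[["average"]], x$precision_summary[["sd"]]))
  invisible(x)
}

#' Published benchmark results used as worked-example inputs
#'
#' The per-phase correct counts (out of 25 test groups per phase), per-node
#' precisions and recalls reported for the four classification models (BP,
#' SVM, PSO-BP, PSO-SVM) in the original amputee-cycling benchmark. These
#' printed values are the inputs from which the derived table cells
#' (recognition rate, F1, G index, precision average / spread) are
#' recomputed by the metric functions.
#'
#' @return list of data frames `counts`, `precision`, `recall`, each with a
#'   `model` column
#' @export
reference_results <- function() {
  models <- c("BP", "SVM", "PSO-BP", "PSO-SVM")
  list(
    counts = data.frame(model = models,
                        pedaling = c(19, 21, 20, 23),
                        lower_buffer = c(15, 22, 20, 24),
                        relaxation = c(21, 17, 21, 23),
                        upper_buffer = c(17, 19, 23, 23),
                        n_total = 100),
    precision = data.frame(model = models,
                           classifier1 = c(72.00, 79.00, 84.00, 93.00),
                           classifier2 = c(70.67, 77.33, 85.33, 93.33),
                           classifier3 = c(76.00, 72.00, 88.00, 92.00)),
    recall = data.frame(model = models,
                        classifier1 = c(76.00, 84.00, 80.00, 92.00),
                        classifier2 = c(60.00, 88.00, 80.00, 96.00),
                        classifier3 = c(84.00, 68.00, 84.00, 92.00)))
}
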
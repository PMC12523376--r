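# Classification metrics from confusion matrices.
#
# All rates are reported on the percent scale. Display rounding is half-up
# to two decimals; computation keeps full precision.

round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Confusion matrix
#'
#' Integer counts with rows = true class and columns = predicted class.
#'
#' @param truth,predicted integer label vectors (1-based).
#' @param class_names character vector of class names; labels index it.
#' @return `k x k` integer matrix of class `"tnv2_confusion"`.
#' @export
confusion_matrix <- function(truth, predicted, class_names) {
  k <- length(class_names)
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted differ in length", call. = FALSE)
  if (any(truth < 1L | truth > k) || any(predicted < 1L | predicted > k))
    stop(sprintf("labels out of range 1..%d", k), call. = FALSE)
  cm <- matrix(0L, k, k, dimnames = list(true = class_names,
                                         predicted = class_names))
  for (i in seq_along(truth))
    cm[truth[i], predicted[i]] <- cm[truth[i], predicted[i]] + 1L
  class(cm) <- c("tnv2_confusion", class(cm))
  cm
}

#' Build a confusion matrix directly from counts
#'
#' Convenience for binary summaries reported as TP/FN/FP/TN with respect to a
#' support (positive) class: row/column 1 is the support class.
#'
#' @param tp,fn,fp,tn integer counts.
#' @param class_names length-2 character vector, support class first.
#' @export
confusion_from_counts <- function(tp, fn, fp, tn,
                                  class_names = c("positive", "negative")) {
  cm <- matrix(as.integer(c(tp, fn, fp, tn)), 2L, 2L, byrow = TRUE,
               dimnames = list(true = class_names, predicted = class_names))
  class(cm) <- c("tnv2_confusion", class(cm))
  cm
}

#' Classification metrics report
#'
#' Computes, from a confusion matrix: per-class precision, recall and F1;
#' their unweighted (macro) means; overall accuracy; for binary problems
#' sensitivity (recall of the support class), specificity (recall of the
#' other class) and the geometric mean `sqrt(sens * spec)`; balanced accuracy
#' (mean of per-class recalls); a 95% accuracy confidence interval (Wilson
#' primary, normal approximation secondary); and a one-sided exact binomial
#' p-value of the accuracy against `baseline`. All rates are percentages.
#' A class never predicted gets precision 0 with a warning.
#'
#' @param cm a [confusion_matrix()].
#' @param support_class index (or name) of the clinically positive class for
#'   sensitivity/specificity; default 1.
#' @param baseline baseline proportion for the binomial test (default 0.5).
#' @return object of class `"tnv2_metrics"`.
#' @export
classification_metrics <- function(cm, support_class = 1L, baseline = 0.5) {
  k <- nrow(cm)
  total <- sum(cm)
  if (total <= 0) stop("empty confusion matrix", call. = FALSE)
  if (is.character(support_class))
    support_class <- match(support_class, rownames(cm))
  tp <- unname(diag(cm))
  pred_pos <- unname(colSums(cm))
  true_pos <- unname(rowSums(cm))
  precision <- ifelse(pred_pos > 0, tp / pred_pos, NA_real_)
  if (anyNA(precision)) {
    warning("class with zero predicted positives; precision set to 0")
    precision[is.na(precision)] <- 0
  }
  recall <- ifelse(true_pos > 0, tp / true_pos, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  accuracy <- sum(tp) / total
  balanced <- mean(recall)
  sens <- spec <- gmean <- NA_real_
  if (k == 2L) {
    sens <- unname(recall[support_class])
    spec <- unname(recall[-support_class])
    gmean <- sqrt(sens * spec)
  }
  inf <- accuracy_inference(sum(tp), total, baseline)
  out <- list(confusion = cm,
              per_class = data.frame(class = rownames(cm),
                                     precision = 100 * precision,
                                     recall = 100 * recall,
                                     f1 = 100 * f1, row.names = NULL),
              macro_precision = 100 * mean(precision),
              macro_recall = 100 * mean(recall),
              macro_f1 = 100 * mean(f1),
              accuracy = 100 * accuracy,
              balanced_accuracy = 100 * balanced,
              sensitivity = 100 * sens, specificity = 100 * spec,
              g_mean = 100 * gmean,
              support_class = rownames(cm)[support_class],
              ci_wilson = 100 * inf$ci_wilson,
              ci_normal = 100 * inf$ci_normal,
              baseline = baseline, p_value = inf$p_value, n = total)
  class(out) <- "tnv2_metrics"
  out
}

#' @export
print.tnv2_metrics <- function(x, digits = 2L, ...) {
  r <- function(v) format(round_half_up(v, digits), nsmall = digits)
  cat(sprintf("Classification metrics (n = %d)\n", x$n))
  cat(sprintf("  accuracy          %s%%  (95%% CI Wilson %s-%s)\n",
              r(x$accuracy), r(x$ci_wilson[1]), r(x$ci_wilson[2])))
  if (!is.na(x$sensitivity)) {
    cat(sprintf("  sensitivity       %s%%  (support: %s)\n",
                r(x$sensitivity), x$support_class))
    cat(sprintf("  specificity       %s%%\n", r(x$specificity)))
    cat(sprintf("  geometric mean    %s%%\n", r(x$g_mean)))
  }
  cat(sprintf("  balanced accuracy %s%%\n", r(x$balanced_accuracy)))
  cat(sprintf("  macro P/R/F1      %s / %s / %s %%\n", r(x$macro_precision),
              r(x$macro_recall), r(x$macro_f1)))
  pc <- x$per_class
  for (i in seq_len(nrow(pc)))
    cat(sprintf("  %-16s P %s  R %s  F1 %s\n", pc$class[i], r(pc$precision[i]),
                r(pc$recall[i]), r(pc$f1[i])))
  cat(sprintf("  binomial p (acc > %.0f%%): %s\n", 100 * x$baseline,
              format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Accuracy inference
#'
#' Exact one-sided binomial tail `P(X >= correct | n, baseline)` and 95%
#' confidence intervals for the accuracy: Wilson score interval (primary) and
#' the normal-approximation (Wald) interval (secondary).
#'
#' @param correct number of correct predictions.
#' @param n number of evaluated items.
#' @param baseline null proportion in (0, 1).
#' @return list with `p_value`, `ci_wilson`, `ci_normal` (proportion scale).
#' @export
accuracy_inference <- function(correct, n, baseline = 0.5) {
  stopifnot(correct >= 0, correct <= n, baseline > 0, baseline < 1)
  p_value <- stats::pbinom(correct - 1, n, baseline, lower.tail = FALSE)
  phat <- correct / n
  z <- stats::qnorm(0.975)
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  ci_wilson <- c(centre - half, centre + half)
  se <- sqrt(phat * (1 - phat) / n)
  ci_normal <- c(phat - z * se, phat + z * se)
  list(p_value = p_value, ci_wilson = pmin(pmax(ci_wilson, 0), 1),
       ci_normal = pmin(pmax(ci_normal, 0), 1))
}

#' One-vs-rest precision-recall curves
#'
#' Sweeps every distinct predicted probability as a threshold (an item is
#' called positive when its class probability is `>=` the threshold);
#' endpoints are included, and the sweep stops at the highest threshold
#' reaching recall 1 (lower thresholds only dilute precision at constant
#' recall). With all scores identical the curve is the single point
#' (precision = class prevalence, recall = 1).
#'
#' @param probs `n x k` row-normalized probability matrix.
#' @param truth integer labels (1-based), at least two distinct classes.
#' @param class_names names for the returned list; defaults to the
#'   probability matrix column names.
#' @return named list (one element per class) of data.frames with columns
#'   `threshold`, `precision`, `recall`.
#' @export
pr_curves <- function(probs, truth, class_names = colnames(probs)) {
  probs <- as.matrix(probs)
  truth <- as.integer(truth)
  if (length(unique(truth)) < 2L)
    stop("precision-recall curves need at least two classes in truth",
         call. = FALSE)
  if (is.null(class_names)) class_names <- paste0("class", seq_len(ncol(probs)))
  out <- list()
  for (ci in seq_len(ncol(probs))) {
    sc <- probs[, ci]
    pos <- truth == ci
    th <- sort(unique(sc), decreasing = TRUE)
    prec <- rec <- numeric(length(th))
    for (i in seq_along(th)) {
      called <- sc >= th[i]
      tp <- sum(called & pos)
      prec[i] <- if (sum(called) > 0) tp / sum(called) else 1
      rec[i] <- if (sum(pos) > 0) tp / sum(pos) else 0
    }
    if (any(rec == 1)) {
      keep <- seq_len(which(rec == 1)[1L])
      th <- th[keep]; prec <- prec[keep]; rec <- rec[keep]
    }
    out[[class_names[ci]]] <- data.frame(threshold = th, precision = prec,
                                         recall = rec)
  }
  out
}
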
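#' Confusion counts at a decision threshold
#'
#' Counts true/false positives/negatives under the `score >= threshold`
#' decision rule.
#'
#' @param labels Binary ground-truth labels (0/1).
#' @param scores Numeric scores, same length as `labels`.
#' @param threshold Decision cutoff (default 0.5).
#' @return A one-row tibble with integer columns `tp`, `tn`, `fp`, `fn`.
#' @examples
#' confusion_counts(c(1, 0), c(0.9, 0.1)) # tp 1, tn 1
#' @export
confusion_counts <- function(labels, scores, threshold = 0.5) {
  if (length(labels) != length(scores)) {
    abort("`labels` and `scores` must have the same length.")
  }
  if (!all(labels %in% c(0, 1))) {
    abort("`labels` must be 0/1.")
  }
  pred <- scores >= threshold
  tibble(
    tp = sum(pred & labels == 1),
    tn = sum(!pred & labels == 0),
    fp = sum(pred & labels == 0),
    fn = sum(!pred & labels == 1)
  )
}

#' Threshold classification metrics from confusion counts
#'
#' Evaluates the five standard metrics:
#' \deqn{Accuracy = (TP+TN)/(TP+FP+TN+FN)}
#' \deqn{Specificity = 1 - FPR = TN/(TN+FP)}
#' \deqn{Precision = TP/(TP+FP)}
#' \deqn{Recall = TPR = TP/(TP+FN)}
#' \deqn{MCC = (TP \cdot TN - FP \cdot FN) / \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#'
#' Any metric whose denominator is zero is undefined and reported as `NA`
#' (never silently 0) — such edge cases are routine on heavily imbalanced
#' test strata.
#'
#' @param counts A one-row tibble/list with `tp`, `tn`, `fp`, `fn` (e.g. from
#'   [confusion_counts()] or [reconstruct_confusion()]).
#' @return A one-row tibble: `accuracy`, `specificity`, `precision`,
#'   `recall`, `mcc`, `fpr`.
#' @export
classification_metrics <- function(counts) {
  tp <- as.numeric(counts$tp)
  tn <- as.numeric(counts$tn)
  fp <- as.numeric(counts$fp)
  fn <- as.numeric(counts$fn)
  if (any(c(tp, tn, fp, fn) < 0)) {
    abort("Confusion counts must be nonnegative.")
  }
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  denom_mcc <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  tibble(
    accuracy = safe_div(tp + tn, tp + fp + tn + fn),
    specificity = safe_div(tn, tn + fp),
    precision = safe_div(tp, tp + fp),
    recall = safe_div(tp, tp + fn),
    mcc = if (denom_mcc == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(denom_mcc),
    fpr = safe_div(fp, tn + fp)
  )
}

#' Reconstruct confusion counts from printed recall/precision
#'
#' Given a published recall and precision together with the test-set class
#' sizes, recovers the integer confusion counts by rounding:
#' `TP = round(recall * n_pos)`, `FN = n_pos - TP`,
#' `FP = round(TP * (1 - precision) / precision)`, `TN = n_neg - FP`.
#' This is the consistency utility used to cross-check published metric
#' tables (e.g. re-deriving accuracy and MCC from recall/precision alone).
#'
#' @param recall,precision Values in (0, 1\].
#' @param n_pos,n_neg Positive / negative test-set sizes.
#' @return A one-row tibble `tp`, `tn`, `fp`, `fn`.
#' @examples
#' reconstruct_confusion(0.589, 0.901, 3404, 34040)
#' @export
reconstruct_confusion <- function(recall, precision, n_pos, n_neg) {
  if (recall <= 0 || recall > 1 || precision <= 0 || precision > 1) {
    abort("`recall` and `precision` must be in (0, 1].")
  }
  if (n_pos <= 0 || n_neg <= 0) {
    abort("`n_pos` and `n_neg` must be positive.")
  }
  tp <- round(recall * n_pos)
  fn <- n_pos - tp
  fp <- round(tp * (1 - precision) / precision)
  if (fp > n_neg) {
    abort(sprintf(
      "Infeasible inputs: implied FP = %d exceeds n_neg = %d.", fp, n_neg
    ))
  }
  tibble(tp = tp, tn = n_neg - fp, fp = fp, fn = fn)
}

#' Precision-recall and ROC curves with their areas
#'
#' Sweeps the decision threshold over the unique scores (using the
#' `score >= threshold` rule) and returns both curves with their areas:
#' AUROC by trapezoidal integration over (FPR, TPR), and AUPR by step-wise
#' (average-precision) integration, which avoids the optimistic linear
#' interpolation of PR points.
#'
#' @param labels Binary ground-truth labels; both classes must be present.
#' @param scores Numeric scores.
#' @return A `ppi_curves` object: list with tibbles `roc`
#'   (`threshold`, `fpr`, `tpr`) and `pr` (`threshold`, `recall`,
#'   `precision`), scalars `auroc` and `aupr`, and `prevalence`.
#' @export
score_curves <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    abort("`labels` and `scores` must have the same length.")
  }
  if (!all(labels %in% c(0, 1)) || length(unique(labels)) < 2) {
    abort("`labels` must contain both classes (0 and 1).")
  }
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # cumulative counts at each threshold = each distinct score (>= rule keeps
  # the last index of every tie block)
  block_end <- which(!duplicated(sc, fromLast = TRUE))
  tp <- cumsum(lab == 1)[block_end]
  fp <- cumsum(lab == 0)[block_end]
  thr <- sc[block_end]
  tpr <- tp / n_pos
  fpr <- fp / n_neg
  precision <- tp / (tp + fp)

  roc <- tibble(
    threshold = c(Inf, thr),
    fpr = c(0, fpr),
    tpr = c(0, tpr)
  )
  auroc <- sum(diff(roc$fpr) * (head(roc$tpr, -1) + roc$tpr[-1]) / 2)
  pr <- tibble(threshold = thr, recall = tpr, precision = precision)
  aupr <- sum(diff(c(0, tpr)) * precision)

  structure(
    list(
      roc = roc, pr = pr,
      auroc = auroc, aupr = aupr,
      prevalence = n_pos / (n_pos + n_neg)
    ),
    class = "ppi_curves"
  )
}

#' @export
print.ppi_curves <- function(x, ...) {
  cat(sprintf(
    "PR/ROC curves: AUPR = %.4f (random floor %.4f), AUROC = %.4f\n",
    x$aupr, x$prevalence, x$auroc
  ))
  invisible(x)
}

#' @describeIn score_curves plot the PR or ROC curve.
#' @param object A `ppi_curves` object.
#' @param curve `"pr"` (default) or `"roc"`.
#' @param ... Unused.
#' @export
autoplot.ppi_curves <- function(object, curve = c("pr", "roc"), ...) {
  curve <- match.arg(curve)
  if (curve == "pr") {
    ggplot2::ggplot(object$pr, ggplot2::aes(.data$recall, .data$precision)) +
      ggplot2::geom_step(direction = "hv") +
      ggplot2::geom_hline(
        yintercept = object$prevalence,
        linetype = "dashed", colour = "grey50"
      ) +
      ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(
        x = "Recall", y = "Precision",
        title = sprintf("Precision-recall curve (AUPR = %.3f)", object$aupr)
      ) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
      ggplot2::geom_line() +
      ggplot2::geom_abline(
        slope = 1, intercept = 0,
        linetype = "dashed", colour = "grey50"
      ) +
      ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
      ggplot2::labs(
        x = "False positive rate", y = "True positive rate",
        title = sprintf("ROC curve (AUROC = %.3f)", object$auroc)
      ) +
      ggplot2::theme_minimal()
  }
}

#' Full evaluation of scored pairs
#'
#' One-stop evaluation: confusion counts and threshold metrics at the given
#' cutoff, plus PR/ROC curves and their areas.
#'
#' @param labels Binary ground-truth labels (0/1).
#' @param scores Numeric scores in \[0, 1\].
#' @param threshold Decision cutoff (default 0.5).
#' @return A `metrics_report` object: list with `counts`, `metrics` (one-row
#'   tibbles), `curves` (a `ppi_curves`), `threshold`, and scalars `aupr`,
#'   `auroc`.
#' @export
evaluate_predictions <- function(labels, scores, threshold = 0.5) {
  counts <- confusion_counts(labels, scores, threshold)
  curves <- score_curves(labels, scores)
  structure(
    list(
      counts = counts,
      metrics = classification_metrics(counts),
      curves = curves,
      threshold = threshold,
      aupr = curves$aupr,
      auroc = curves$auroc
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("Evaluation at threshold %.3g:\n", x$threshold))
  cat(sprintf(
    "  accuracy %.3f | specificity %.3f | precision %.3f | recall %.3f | MCC %.3f\n",
    m$accuracy, m$specificity, m$precision, m$recall, m$mcc
  ))
  cat(sprintf("  AUPR %.4f | AUROC %.4f\n", x$aupr, x$auroc))
  invisible(x)
}

#' @describeIn evaluate_predictions long tibble of all scalar metrics.
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
tidy.metrics_report <- function(x, ...) {
  wide <- glance(x)
  tidyr::pivot_longer(wide, dplyr::everything(),
    names_to = "metric", values_to = "value"
  )
}

#' @describeIn evaluate_predictions one-row tibble of all scalar metrics.
#' @export
glance.metrics_report <- function(x, ...) {
  dplyr::bind_cols(
    x$metrics,
    tibble(aupr = x$aupr, auroc = x$auroc, threshold = x$threshold),
    x$counts
  )
}
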
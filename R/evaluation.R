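# Regression and classification metrics, their fold-level aggregation
# (mean +/- sd and the Student-t 95% confidence interval of the MSE), and
# per-cell-line breakdowns.

#' Regression metrics
#'
#' @param pred,truth Equal-length numeric vectors.
#' @return List with `mse`, `rmse` (= sqrt(mse)) and `pearson`.
#' @export
regression_metrics <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1L)
  if (stats::sd(truth) == 0) stop("constant truth: Pearson correlation undefined")
  mse <- mean((pred - truth)^2)
  list(mse = mse, rmse = sqrt(mse),
       pearson = as.numeric(stats::cor(pred, truth)))
}

#' Student-t confidence interval of the fold-level MSE
#'
#' `mean +/- t_{0.975, n-1} * sd / sqrt(n)` with the sample sd (n-1
#' denominator); symmetric around the mean.
#'
#' @param fold_mses Numeric vector of per-fold MSE values (length >= 2).
#' @param level Confidence level (default 0.95).
#' @return List with `mean`, `sd`, `lo`, `hi`.
#' @export
mse_confidence_interval <- function(fold_mses, level = 0.95) {
  n <- length(fold_mses)
  if (n < 2L) stop("need at least two folds for a confidence interval")
  m <- mean(fold_mses)
  s <- stats::sd(fold_mses)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1L) * s / sqrt(n)
  list(mean = m, sd = s, lo = m - half, hi = m + half)
}

#' ROC-AUC of a score against a binary label
#'
#' Rank-based (Mann-Whitney) area with average ranks for ties, equivalent to
#' the trapezoidal area under the ROC curve.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param positive Logical vector (or 0/1) marking positives.
#' @return Area in \[0, 1\].
#' @export
roc_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L) stop("ROC-AUC undefined: single-class truth")
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - np * (np + 1) / 2) / (np * nn)
}

#' PR-AUC of a score against a binary label
#'
#' Trapezoidal area under the precision-recall curve traced over the
#' distinct score thresholds (descending), anchored at recall 0 with the
#' precision of the highest-scoring block.
#'
#' @inheritParams roc_auc
#' @return Area in \[0, 1\].
#' @export
pr_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  np <- sum(positive); nn <- sum(!positive)
  if (np == 0L || nn == 0L) stop("PR-AUC undefined: single-class truth")
  ord <- order(scores, decreasing = TRUE)
  pos <- positive[ord]
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  # evaluate only at the last index of each tied-score block
  s_sorted <- scores[ord]
  last_of_block <- c(s_sorted[-1] != s_sorted[-length(s_sorted)], TRUE)
  tp <- tp[last_of_block]; fp <- fp[last_of_block]
  precision <- tp / (tp + fp)
  recall <- tp / np
  recall <- c(0, recall)
  precision <- c(precision[1L], precision)
  sum(diff(recall) * (precision[-1L] + precision[-length(precision)]) / 2)
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between predicted and true labels, with chance
#' agreement from the marginal label frequencies.
#'
#' @param pred,truth Factors (or characters) over the same label set.
#' @return Kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(pred, truth) {
  levels_all <- union(levels(factor(truth)), levels(factor(pred)))
  p <- factor(as.character(pred), levels = levels_all)
  t <- factor(as.character(truth), levels = levels_all)
  tab <- table(p, t)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (pe == 1) return(0)
  (po - pe) / (1 - pe)
}

#' Classification metrics for the three-class synergy task
#'
#' Accuracy and Cohen's kappa are computed over the three-class argmax
#' predictions; precision is that of the synergistic class (one-vs-rest);
#' ROC-AUC and PR-AUC use the synergistic-class probability against the
#' binary synergistic-vs-rest truth.
#'
#' @param class_probs n x 3 matrix of class probabilities with columns
#'   (antagonistic, additive, synergistic).
#' @param labels True labels (factor/character over the three classes).
#' @return List with `accuracy`, `precision`, `kappa`, `roc_auc`, `pr_auc`.
#'   `precision` is `NA` when no sample is predicted synergistic.
#' @export
classification_metrics <- function(class_probs, labels) {
  stopifnot(is.matrix(class_probs), ncol(class_probs) == 3L)
  labels <- factor(as.character(labels), levels = SYNERGY_CLASSES)
  stopifnot(nrow(class_probs) == length(labels))
  pred <- factor(SYNERGY_CLASSES[max.col(class_probs, ties.method = "first")],
                 levels = SYNERGY_CLASSES)
  acc <- mean(pred == labels)
  kap <- cohen_kappa(pred, labels)
  pos_true <- labels == "synergistic"
  pos_pred <- pred == "synergistic"
  precision <- if (any(pos_pred)) sum(pos_pred & pos_true) / sum(pos_pred) else NA_real_
  list(accuracy = acc,
       precision = precision,
       kappa = kap,
       roc_auc = roc_auc(class_probs[, 3L], pos_true),
       pr_auc = pr_auc(class_probs[, 3L], pos_true))
}

#' Fold report: all metrics for one test fold
#'
#' @param score_pred Predicted synergy scores.
#' @param class_probs n x 3 predicted class probabilities.
#' @param combos The test-fold combination table (truth).
#' @param per_cell Also compute per-cell-line breakdowns (default `TRUE`).
#' @return List of class `fold_report` with the regression metrics, the
#'   classification metrics, `n`, and (optionally) `per_cell_line`.
#' @export
fold_report <- function(score_pred, class_probs, combos, per_cell = TRUE) {
  reg <- regression_metrics(score_pred, combos$loewe_score)
  cls <- classification_metrics(class_probs, combos$label)
  out <- c(reg, cls, list(n = nrow(combos)))
  if (per_cell) {
    out$per_cell_line <- per_group_metrics(score_pred, class_probs, combos,
                                           combos$cell_id)
  }
  structure(out, class = "fold_report")
}

#' Per-group (cell-line) metrics
#'
#' Regression metrics and synergistic-class precision per group; a group for
#' which a metric's preconditions fail (constant truth, single-class truth)
#' reports `NA` for that metric with a `reason`.
#'
#' @param score_pred,class_probs Predictions (as in [fold_report()]).
#' @param combos Combination table (truth).
#' @param group Grouping vector (typically `combos$cell_id`).
#' @return Named list per group: `n`, `mse`, `rmse`, `pearson`, `precision`,
#'   `roc_auc`, and possibly `reason`.
#' @export
per_group_metrics <- function(score_pred, class_probs, combos, group) {
  out <- list()
  for (g in unique(group)) {
    i <- which(group == g)
    rec <- list(n = length(i))
    rec$mse <- mean((score_pred[i] - combos$loewe_score[i])^2)
    rec$rmse <- sqrt(rec$mse)
    rec$pearson <- if (length(i) >= 2L && stats::sd(combos$loewe_score[i]) > 0)
      as.numeric(stats::cor(score_pred[i], combos$loewe_score[i])) else NA_real_
    labs <- factor(as.character(combos$label[i]), levels = SYNERGY_CLASSES)
    pred <- factor(SYNERGY_CLASSES[max.col(class_probs[i, , drop = FALSE],
                                           ties.method = "first")],
                   levels = SYNERGY_CLASSES)
    pos_pred <- pred == "synergistic"; pos_true <- labs == "synergistic"
    rec$precision <- if (any(pos_pred)) sum(pos_pred & pos_true) / sum(pos_pred) else NA_real_
    rec$roc_auc <- if (any(pos_true) && any(!pos_true))
      roc_auc(class_probs[i, 3L], pos_true) else NA_real_
    if (anyNA(c(rec$pearson, rec$precision, rec$roc_auc))) {
      rec$reason <- "metric preconditions unmet for this group (constant or single-class truth, or no positive prediction)"
    }
    out[[g]] <- rec
  }
  out
}

#' Aggregate fold reports
#'
#' Mean and sd of every scalar metric over folds, plus the Student-t 95%
#' confidence interval of the MSE.
#'
#' @param reports List of `fold_report` objects.
#' @return List with `mean`, `sd` (named lists over metrics), `mse_ci`
#'   and `n_folds`.
#' @export
summarize_folds <- function(reports) {
  stopifnot(length(reports) >= 1L)
  metrics <- c("mse", "rmse", "pearson", "accuracy", "precision", "kappa",
               "roc_auc", "pr_auc")
  vals <- lapply(metrics, function(m)
    vapply(reports, function(r) as.numeric(r[[m]]), numeric(1)))
  names(vals) <- metrics
  list(mean = lapply(vals, function(v) mean(v, na.rm = TRUE)),
       sd = lapply(vals, function(v) stats::sd(v[!is.na(v)])),
       mse_ci = if (length(reports) >= 2L) mse_confidence_interval(vals$mse) else NULL,
       n_folds = length(reports))
}
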
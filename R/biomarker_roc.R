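#' Area under the ROC curve
#'
#' Computed from the rank-sum statistic: the probability that a random
#' positive outscores a random negative, with ties credited 0.5.
#'
#' @param scores numeric vector of classifier scores.
#' @param truth logical vector (`TRUE` = positive class), same length.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth) || any(is.na(truth))) {
    stop("scores and truth must be aligned, truth binary", call. = FALSE)
  }
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Ordered `(FPR, TPR)` points from `(0, 0)` to `(1, 1)`, one per distinct
#' score threshold (descending). `direction = "LOW_IN_ETP"` negates the
#' scores first, so markers *lower* in the positive class trace the same
#' curve as their negated counterpart. The trapezoidal area under the
#' returned points equals [auc()] of the aligned scores.
#'
#' @param scores,truth as in [auc()].
#' @param direction `"HIGH_IN_ETP"` (default) or `"LOW_IN_ETP"`.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, truth, direction = c("HIGH_IN_ETP", "LOW_IN_ETP")) {
  direction <- match.arg(direction)
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  s <- if (direction == "LOW_IN_ETP") -scores else scores
  thr <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(thr, function(ct) sum(s >= ct & truth) / n1, 0)
  fpr <- vapply(thr, function(ct) sum(s >= ct & !truth) / n0, 0)
  data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Youden-optimal classification cutoff
#'
#' Maximizes Youden's J = TPR - FPR over midpoints between adjacent
#' distinct scores (ties resolved toward the lower cutoff). Samples score
#' positive when strictly above the cutoff (below, for
#' `direction = "LOW_IN_ETP"`; the returned cutoff is always on the
#' original score scale). `rule = "closest"` instead picks the cutoff
#' whose ROC point is nearest to the (0, 1) corner.
#'
#' @param scores,truth,direction as in [roc_curve()].
#' @param rule `"youden"` (default) or `"closest"` (closest to top-left).
#' @return scalar cutoff.
#' @export
optimal_cutoff <- function(scores, truth,
                           direction = c("HIGH_IN_ETP", "LOW_IN_ETP"),
                           rule = c("youden", "closest")) {
  direction <- match.arg(direction)
  rule <- match.arg(rule)
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  s <- if (direction == "LOW_IN_ETP") -scores else scores
  u <- sort(unique(s))
  cands <- if (length(u) >= 2) (u[-1] + u[-length(u)]) / 2 else u
  tpr <- vapply(cands, function(ct) sum(s > ct & truth) / n1, 0)
  fpr <- vapply(cands, function(ct) sum(s > ct & !truth) / n0, 0)
  crit <- if (rule == "youden") tpr - fpr else -((1 - tpr)^2 + fpr^2)
  best <- cands[which(crit == max(crit))]
  ct <- min(best)
  if (direction == "LOW_IN_ETP") -ct else ct
}

#' Evaluate one gene as an ETP / non-ETP classifier
#'
#' Assembles direction-aligned AUC, the optimal cutoff and a confusion
#' matrix expressed as percentages of each truth class: `TP` is the % of
#' ETP cases on the marker's high side of the cutoff (low side for
#' `LOW_IN_ETP` markers, the CDH2-style flip), `FP` the % of non-ETP
#' cases there, with `TP + FN = 100` and `FP + TN = 100`.
#'
#' @param expr expression matrix.
#' @param labels a [cohort_labels()] object.
#' @param gene gene symbol to evaluate.
#' @param direction `"HIGH_IN_ETP"` or `"LOW_IN_ETP"`.
#' @param rule cutoff rule, see [optimal_cutoff()].
#' @return list of class `classifier_eval`: `gene`, `direction`, `auc`,
#'   `cutoff`, `confusion` (named TP/FN/FP/TN percentages).
#' @export
evaluate_biomarker <- function(expr, labels,
                               gene, direction = c("HIGH_IN_ETP", "LOW_IN_ETP"),
                               rule = c("youden", "closest")) {
  direction <- match.arg(direction)
  rule <- match.arg(rule)
  validate_expression_matrix(expr)
  gene <- toupper(gene)
  if (!gene %in% rownames(expr)) {
    stop("gene absent from matrix: ", gene, call. = FALSE)
  }
  .check_groups(expr, labels, min_n = 1)
  truth <- colnames(expr) %in% group_samples(labels, "ETP")
  scores <- expr[gene, ]
  aligned <- if (direction == "LOW_IN_ETP") -scores else scores
  a <- auc(aligned, truth)
  cutoff <- optimal_cutoff(scores, truth, direction, rule)
  pos_side <- if (direction == "LOW_IN_ETP") scores < cutoff else scores > cutoff
  tp <- 100 * sum(pos_side & truth) / sum(truth)
  fp <- 100 * sum(pos_side & !truth) / sum(!truth)
  structure(list(gene = gene, direction = direction, auc = a,
                 cutoff = cutoff,
                 confusion = c(TP = tp, FN = 100 - tp, FP = fp,
                               TN = 100 - fp)),
            class = "classifier_eval")
}
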
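#' Confusion counts at a threshold
#'
#' A cell is predicted present iff its score is at or above `t` (closed
#' lower bound).
#'
#' @param scores_pos scores at true positives (>= 1 value).
#' @param scores_neg scores at true negatives (>= 1 value).
#' @param t threshold.
#' @return list with integer fields `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_at_threshold <- function(scores_pos, scores_neg, t) {
  if (length(scores_pos) < 1 || length(scores_neg) < 1)
    stop("need at least one positive and one negative score")
  list(tp = sum(scores_pos >= t), fn = sum(scores_pos < t),
       fp = sum(scores_neg >= t), tn = sum(scores_neg < t))
}

#' Confusion-derived metrics
#'
#' Recall = TP/(TP+FN); false positive rate = FP/(FP+TN); precision =
#' TP/(TP+FP), undefined (`NA`) when nothing is predicted present; F1 =
#' 2 * precision * recall / (precision + recall), `NA` when precision is
#' undefined or precision + recall = 0.
#'
#' @param c confusion counts from [confusion_at_threshold()].
#' @return list with fields `recall`, `fpr`, `precision`, `f1`.
#' @export
metrics <- function(c) {
  recall <- c$tp / (c$tp + c$fn)
  fpr <- c$fp / (c$fp + c$tn)
  precision <- if (c$tp + c$fp == 0) NA_real_ else c$tp / (c$tp + c$fp)
  f1 <- if (is.na(precision) || precision + recall == 0) NA_real_
        else 2 * precision * recall / (precision + recall)
  list(recall = recall, fpr = fpr, precision = precision, f1 = f1)
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability that a positive outscores a
#' negative, with ties counted half (midranks).
#'
#' @param scores_pos,scores_neg numeric score vectors (>= 1 each).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores_pos, scores_neg) {
  np <- length(scores_pos); nn <- length(scores_neg)
  if (np < 1 || nn < 1) stop("need at least one positive and one negative score")
  r <- rank(c(scores_pos, scores_neg))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# operating points of the PR curve at every distinct score threshold,
# ordered by increasing recall (decreasing threshold)
pr_points <- function(scores_pos, scores_neg) {
  thr <- sort(unique(c(scores_pos, scores_neg)), decreasing = TRUE)
  np <- length(scores_pos)
  recall <- precision <- numeric(length(thr))
  for (i in seq_along(thr)) {
    tp <- sum(scores_pos >= thr[i])
    fp <- sum(scores_neg >= thr[i])
    recall[i] <- tp / np
    precision[i] <- if (tp + fp == 0) NA_real_ else tp / (tp + fp)
  }
  keep <- !is.na(precision)
  list(recall = recall[keep], precision = precision[keep])
}

#' Area under the precision-recall curve
#'
#' The curve is evaluated at every distinct observed score used as a
#' threshold and integrated by the trapezoid rule in recall, linearly
#' interpolating between operating points. Precision as recall tends to
#' 0 is taken as the precision at the highest threshold.
#'
#' @param scores_pos,scores_neg numeric score vectors (>= 1 each).
#' @return AUC_PR in `(0, 1]`.
#' @export
pr_auc <- function(scores_pos, scores_neg) {
  if (length(scores_pos) < 1 || length(scores_neg) < 1)
    stop("need at least one positive and one negative score")
  pts <- pr_points(scores_pos, scores_neg)
  r <- c(0, pts$recall)
  p <- c(pts$precision[1], pts$precision)
  sum(diff(r) * (p[-1] + p[-length(p)]) / 2)
}

#' Maximum F1-score over all observed thresholds
#'
#' Scans every distinct observed score as a threshold; on ties the
#' lowest achieving threshold is returned.
#'
#' @param scores_pos,scores_neg numeric score vectors (>= 1 each).
#' @return list with fields `max_f1` and `threshold`.
#' @export
max_f1 <- function(scores_pos, scores_neg) {
  if (length(scores_pos) < 1 || length(scores_neg) < 1)
    stop("need at least one positive and one negative score")
  thr <- sort(unique(c(scores_pos, scores_neg)))
  best <- -Inf; best_t <- thr[1]
  for (t in thr) {
    f1 <- metrics(confusion_at_threshold(scores_pos, scores_neg, t))$f1
    if (!is.na(f1) && f1 > best + 1e-15) {
      best <- f1; best_t <- t
    }
  }
  list(max_f1 = best, threshold = best_t)
}

#' Thresholds for converting a prediction into binary range maps
#'
#' The no-omission threshold (every presence cell still predicted
#' present) is the minimum predicted value over presence cells; the
#' max-F1 threshold maximizes F1 of presence cells against the remaining
#' native background.
#'
#' @param prediction numeric prediction over the native cells (same order
#'   as `mask_cells(native)`).
#' @param presence_cells integer cell ids of the presence cells.
#' @param native a [region_mask()].
#' @return list with fields `no_omission` and `max_f1`.
#' @export
binary_thresholds <- function(prediction, presence_cells, native) {
  cells <- mask_cells(native)
  idx <- match(presence_cells, cells)
  if (anyNA(idx)) stop("presence cells outside the native region")
  pos <- prediction[idx]
  neg <- prediction[-idx]
  list(no_omission = min(pos),
       max_f1 = if (length(neg) > 0) max_f1(pos, neg)$threshold else min(pos))
}

#' Evaluate a prediction against presence-background data or a reference range
#'
#' Positives are the member cells of `positives_mask` (presence cells, or
#' a rasterized expert reference range); negatives are the remaining
#' native cells. Computes ROC-AUC, PR-AUC, maximum F1 and the two binary
#' thresholds.
#'
#' @param prediction numeric prediction over native cells (same order as
#'   `mask_cells(native)`).
#' @param positives_mask a [region_mask()] (subset of `native`) or an
#'   integer vector of positive cell ids.
#' @param native a [region_mask()].
#' @param mode `"presence_background"` or `"expert_range"` (recorded in
#'   the report).
#' @return object of class `eval_report` with fields `auc`, `auc_pr`,
#'   `max_f1`, `threshold_no_omission`, `threshold_max_f1`, `reference`.
#' @export
evaluate <- function(prediction, positives_mask, native,
                     mode = c("presence_background", "expert_range")) {
  mode <- match.arg(mode)
  pos_cells <- if (inherits(positives_mask, "region_mask"))
    mask_cells(positives_mask) else as.integer(positives_mask)
  cells <- mask_cells(native)
  if (!all(pos_cells %in% cells)) stop("positives must be native cells")
  idx <- match(pos_cells, cells)
  pos <- prediction[idx]
  neg <- prediction[-idx]
  if (length(pos) == 0 || length(neg) == 0)
    stop("degenerate class balance")
  mf <- max_f1(pos, neg)
  structure(list(auc = roc_auc(pos, neg),
                 auc_pr = pr_auc(pos, neg),
                 max_f1 = mf$max_f1,
                 threshold_no_omission = min(pos),
                 threshold_max_f1 = mf$threshold,
                 reference = mode),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report:%s> AUC %.3f, AUC_PR %.3f, max F1 %.3f\n",
              x$reference, x$auc, x$auc_pr, x$max_f1))
  invisible(x)
}
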
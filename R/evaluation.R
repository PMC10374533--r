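#' Q75 summary of the 16 per-segment outputs
#'
#' The classifier emits 16 sigmoid values per class per 5-s segment.  The
#' segment-level score is the mean of the values lying between the 75th and
#' 100th percentile, i.e. the top `ceiling(16 * 0.25) = 4` values.  Target
#' sounds repeat within a segment, so pooling several high outputs
#' suppresses spurious single-column spikes.
#'
#' @param raw numeric vector of 16 values in \[0, 1\].
#' @param top_frac fraction of values pooled (default 0.25).
#' @return scalar in \[0, 1\].
#' @export
q75_summarize <- function(raw, top_frac = 0.25) {
  if (length(raw) != 16L)
    stop("q75_summarize expects 16 values, got ", length(raw))
  if (any(!is.finite(raw))) stop("scores must be finite")
  k <- ceiling(length(raw) * top_frac)
  mean(sort(raw, decreasing = TRUE)[seq_len(k)])
}

#' Precision-recall curve
#'
#' Thresholds are the sorted unique scores (ascending); a segment is
#' predicted positive when `score >= threshold` (closed bound, applied
#' consistently across the pipeline).  Recall is non-increasing in the
#' threshold.
#'
#' @param labels binary vector (1 = positive).
#' @param scores numeric vector of the same length (Q75 per segment).
#' @param class_name optional class label for printing/plotting.
#' @return data.frame of class `pam_pr_curve` with columns `threshold,
#'   ppv, tpr`, plus attributes `n_pos`, `n`, `class_name`.
#' @export
pr_curve <- function(labels, scores, class_name = NA_character_) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels != 0)
  n_pos <- sum(labels)
  if (n_pos == 0L) stop("pr_curve needs at least one positive label")
  th <- sort(unique(scores))
  # counts via cumulative sums over score-sorted labels
  ppv <- tpr <- numeric(length(th))
  for (i in seq_along(th)) {
    pred <- scores >= th[i]
    tp <- sum(labels[pred])
    ppv[i] <- if (any(pred)) tp / sum(pred) else 1
    tpr[i] <- tp / n_pos
  }
  out <- data.frame(threshold = th, ppv = ppv, tpr = tpr)
  class(out) <- c("pam_pr_curve", "data.frame")
  attr(out, "n_pos") <- n_pos
  attr(out, "n") <- length(labels)
  attr(out, "class_name") <- class_name
  out
}

#' Average precision from a PR curve
#'
#' Step-sum over the threshold-ordered curve:
#' `AP = sum_t [TPR(t) - TPR(t+1)] * PPV(t)` with the boundary convention
#' `TPR(T) = 0`, `PPV(T) = 1` beyond the last threshold.
#'
#' @param curve a [pr_curve].
#' @return AP in \[0, 1\].
#' @export
average_precision <- function(curve) {
  tpr <- c(curve$tpr, 0)
  ppv <- curve$ppv
  sum((tpr[-length(tpr)] - tpr[-1]) * ppv)
}

#' Micro-averaged mean average precision
#'
#' Per-segment labels and scores from all classes are pooled into a single
#' binary problem, one PR curve is computed, and its AP is reported; the
#' pooling accounts for class imbalance.
#'
#' @param labels binary matrix (segments x classes) or list of vectors.
#' @param scores numeric matrix/list matching `labels`.
#' @return micro mAP in \[0, 1\].
#' @export
micro_map <- function(labels, scores) {
  if (is.list(labels)) { labels <- do.call(c, labels); scores <- do.call(c, scores) }
  average_precision(pr_curve(as.numeric(labels), as.numeric(scores)))
}

#' Decision threshold at the precision = recall point
#'
#' Returns the curve threshold minimizing `|PPV - TPR|`; ties break toward
#' the higher threshold.
#'
#' @param curve a [pr_curve].
#' @return scalar threshold.
#' @export
select_threshold <- function(curve) {
  d <- abs(curve$ppv - curve$tpr)
  best <- which(d == min(d))
  curve$threshold[max(best)]
}

#' TPR / TNR spot check on sampled classified segments
#'
#' Emulates the per-site validation in which 60 randomly selected
#' classified segments are reviewed: by default 30 are drawn from the
#' predicted positives and 30 from the predicted negatives (seeded,
#' without replacement), and TPR = TP/(TP+FN), TNR = TN/(TN+FP) are
#' computed from their true labels.  When a stratum holds fewer segments
#' than requested, all of it is used with a warning; when a rate is
#' undefined (no true positives/negatives among the sample) it is `NaN`
#' and flagged.
#'
#' @param labels binary truth vector.
#' @param scores segment scores.
#' @param threshold decision threshold (predicted positive when
#'   `score >= threshold`).
#' @param n_sample total segments reviewed (default 60).
#' @param seed RNG seed for the draw.
#' @param stratified draw `n_sample/2` from each side of the threshold
#'   (default) rather than uniformly.
#' @return list with `tpr`, `tnr`, `counts` (tp, fp, tn, fn) and
#'   `undefined` flags.
#' @export
tpr_tnr_at <- function(labels, scores, threshold, n_sample = 60L, seed = 1L,
                       stratified = TRUE) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels != 0)
  pred <- scores >= threshold
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pick <- function(pool, k) {
    if (length(pool) < k) {
      warning("stratum holds ", length(pool), " < ", k,
              " segments; using all")
      pool
    } else sample(pool, k)
  }
  if (stratified) {
    half <- n_sample %/% 2L
    sel <- c(pick(which(pred), half), pick(which(!pred), half))
  } else {
    sel <- pick(seq_along(labels), n_sample)
  }
  l <- labels[sel]; p <- pred[sel]
  tp <- sum(l == 1 & p); fp <- sum(l == 0 & p)
  tn <- sum(l == 0 & !p); fn <- sum(l == 1 & !p)
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NaN
  tnr <- if (tn + fp > 0) tn / (tn + fp) else NaN
  if (!any(pred)) warning("no predicted positives at threshold ", threshold,
                          ": TPR undefined")
  list(tpr = tpr, tnr = tnr,
       counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
       undefined = c(tpr = !is.finite(tpr), tnr = !is.finite(tnr)))
}

#' @export
print.pam_pr_curve <- function(x, ...) {
  cn <- attr(x, "class_name")
  cat(sprintf("PR curve%s: %d thresholds, %d/%d positives, AP = %.4f\n",
              if (is.na(cn)) "" else paste0(" [", cn, "]"),
              nrow(x), attr(x, "n_pos"), attr(x, "n"),
              average_precision(x)))
  invisible(x)
}

#' @export
plot.pam_pr_curve <- function(x, ...) {
  graphics::plot(x$tpr, x$ppv, type = "s", xlim = c(0, 1), ylim = c(0, 1),
                 xlab = "Recall (TPR)", ylab = "Precision (PPV)",
                 main = attr(x, "class_name"), ...)
  invisible(x)
}

#' Evaluation report for a model on a labeled set
#'
#' @param labels segments x classes binary matrix.
#' @param scores segments x classes Q75 score matrix.
#' @param classes class names (defaults to `colnames(labels)`).
#' @return list of class `pam_eval_report`: per-class AP and PR curves,
#'   micro mAP, selected thresholds.
#' @export
eval_report <- function(labels, scores, classes = colnames(labels)) {
  if (is.null(classes)) classes <- paste0("class", seq_len(ncol(labels)))
  curves <- lapply(seq_along(classes), function(k)
    pr_curve(labels[, k], scores[, k], classes[k]))
  names(curves) <- classes
  ap <- vapply(curves, average_precision, 0)
  th <- vapply(curves, select_threshold, 0)
  out <- list(classes = classes, curves = curves, ap = ap,
              micro_map = micro_map(labels, scores), thresholds = th)
  class(out) <- "pam_eval_report"
  out
}

#' @export
print.pam_eval_report <- function(x, ...) {
  cat("Model evaluation\n")
  for (k in seq_along(x$classes))
    cat(sprintf("  %-6s AP = %.4f  (PPV=TPR threshold %.3f)\n",
                x$classes[k], x$ap[k], x$thresholds[k]))
  cat(sprintf("  micro mAP = %.4f\n", x$micro_map))
  invisible(x)
}

#' Relative gain in average precision
#'
#' Percentage increase from an initial to a final mean AP, truncated (not
#' rounded) to one decimal as reported in monitoring summaries: e.g. a
#' 0.90 to 0.95 improvement is a 5.5 percent gain.
#'
#' @param ap_initial,ap_final mean AP before and after retraining.
#' @return percentage gain, truncated to one decimal.
#' @export
relative_ap_gain <- function(ap_initial, ap_final) {
  stopifnot(ap_initial > 0)
  trunc((ap_final - ap_initial) / ap_initial * 1000) / 10
}
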
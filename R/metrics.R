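# Evaluation metrics: confusion-count summaries, ROC/AUC, fold aggregation.

#' Classification metrics from confusion counts
#'
#' Computes accuracy, precision, recall and F1 from the four confusion
#' counts. A metric whose denominator is zero (e.g. precision with no
#' predicted positives) is reported as `NA` with a warning, never silently as
#' zero, and is excluded from fold aggregation by [aggregate_folds()].
#'
#' @param tp,fp,tn,fn non-negative integer counts of true positives, false
#'   positives, true negatives and false negatives.
#' @return a list of class `metric_set` with `accuracy`, `precision`,
#'   `recall` and `f1`.
#' @export
classification_metrics <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != as.integer(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  total <- sum(counts)
  if (total < 1) stop("at least one prediction is required", call. = FALSE)
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " is undefined (zero denominator)", call. = FALSE)
      return(NA_real_)
    }
    num / den
  }
  accuracy <- (tp + tn) / total
  precision <- safe_div(tp, tp + fp, "precision")
  recall <- safe_div(tp, tp + fn, "recall")
  f1 <- if (is.na(precision) || is.na(recall)) {
    warning("F1 is undefined", call. = FALSE)
    NA_real_
  } else if (precision + recall == 0) {
    warning("F1 is undefined (precision + recall = 0)", call. = FALSE)
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(accuracy = accuracy, precision = precision, recall = recall,
                 f1 = f1),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  vals <- unlist(x)
  cat("<metric_set>\n")
  for (m in names(vals)) cat(sprintf("  %-9s %s\n", m,
                                     ifelse(is.na(vals[m]), "undefined",
                                            sprintf("%.4f", vals[m]))))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Builds the ROC curve by sweeping score thresholds from high to low (tied
#' scores move as one block) and integrates it by the trapezoidal rule. With
#' ties handled this way the AUC equals the pairwise concordance probability
#' P(score_case > score_control) + 0.5 P(tie) over all case-control pairs.
#' The full `[0, 1]` range is reported; a classifier worse than chance can
#' score below 0.5.
#'
#' @param labels binary vector (1 = case, 0 = control) with both classes
#'   present.
#' @param scores numeric vector of case-likeness scores, same length.
#' @return a list with `roc` (data.frame of `fpr`, `tpr` starting at (0,0)
#'   and ending at (1,1)) and `auc`.
#' @export
roc_auc <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length", call. = FALSE)
  }
  labels <- check_binary_labels(labels)
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- labels[ord] == 1L
  n1 <- sum(pos); n0 <- length(pos) - n1
  # collapse tied scores into single threshold steps
  block_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(pos)[block_end]
  fp <- cumsum(!pos)[block_end]
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1L) + utils::tail(tpr, -1L)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Aggregate per-fold metrics
#'
#' Arithmetic mean and sample standard deviation (denominator n - 1) of each
#' metric across folds. Undefined (`NA`) fold values are excluded with a
#' message recording how many were dropped; a metric undefined in every fold
#' stays `NA`.
#'
#' @param per_fold list (length >= 2) of named numeric vectors or
#'   `metric_set` objects, one per fold.
#' @return data.frame with columns `metric`, `mean`, `sd`, `n_folds`
#'   (defined folds).
#' @export
aggregate_folds <- function(per_fold) {
  if (length(per_fold) < 2L) stop("need at least two folds", call. = FALSE)
  rows <- lapply(per_fold, function(f) unlist(f, use.names = TRUE))
  metrics <- names(rows[[1L]])
  vals <- do.call(rbind, rows)
  out <- data.frame(metric = metrics,
                    mean = NA_real_, sd = NA_real_,
                    n_folds = NA_integer_, stringsAsFactors = FALSE)
  for (i in seq_along(metrics)) {
    v <- vals[, i]
    n_na <- sum(is.na(v))
    if (n_na > 0 && n_na < length(v)) {
      message(metrics[i], ": excluded ", n_na, " undefined fold value(s)")
    }
    v <- v[!is.na(v)]
    out$n_folds[i] <- length(v)
    if (length(v)) {
      out$mean[i] <- mean(v)
      out$sd[i] <- if (length(v) > 1L) sd(v) else NA_real_
    }
  }
  out
}

# Metrics of hard predictions at a score threshold, plus AUC.
score_metrics <- function(y, scores, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  m <- suppressWarnings(classification_metrics(
    tp = sum(pred == 1L & y == 1L), fp = sum(pred == 1L & y == 0L),
    tn = sum(pred == 0L & y == 0L), fn = sum(pred == 0L & y == 1L)))
  c(unlist(m), auc = roc_auc(y, scores)$auc)
}
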
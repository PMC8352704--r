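# Confusion-matrix accounting and the recognition / sensitivity /
# specificity triple, with COPD (label 1) as the positive class:
#   recognition = (TP + TN) / (TP + TN + FP + FN)
#   sensitivity = TP / (TP + FN)
#   specificity = TN / (TN + FP)
# An empty truth margin (no positives, or no negatives) makes the matching
# ratio undefined; it is reported as NA with a warning, never as a silent 0.

#' Confusion counts from predicted and true labels
#'
#' @param predicted,truth equal-length integer vectors over \{0, 1\}.
#' @param positive the positive-class label (default 1 = COPD).
#' @return An object of class `confusion_counts`: list `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(predicted, truth, positive = 1L) {
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length")
  if (!all(c(predicted, truth) %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  pos <- truth == positive
  pp <- predicted == positive
  structure(list(TP = sum(pp & pos), FP = sum(pp & !pos),
                 TN = sum(!pp & !pos), FN = sum(!pp & pos)),
            class = "confusion_counts")
}

#' Recognition, sensitivity and specificity from confusion counts
#'
#' @param counts a [confusion()] result, or any list with integer fields
#'   `TP`, `FP`, `TN`, `FN`.
#' @return An object of class `metrics_triple`: list `recognition`,
#'   `sensitivity`, `specificity`, each in \[0,1\] (or `NA` for an undefined
#'   margin).
#' @export
metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  if (any(c(tp, fp, tn, fn) < 0)) stop("counts must be nonnegative")
  total <- tp + fp + tn + fn
  if (total < 1) stop("at least one sample required")
  sens <- if (tp + fn == 0) {
    warning("no positive samples in truth: sensitivity undefined"); NA_real_
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) {
    warning("no negative samples in truth: specificity undefined"); NA_real_
  } else tn / (tn + fp)
  structure(list(recognition = (tp + tn) / total,
                 sensitivity = sens, specificity = spec),
            class = "metrics_triple")
}

#' @export
print.metrics_triple <- function(x, ...) {
  cat(sprintf("recognition %.1f%%  sensitivity %s  specificity %s\n",
              100 * x$recognition,
              if (is.na(x$sensitivity)) "NA" else sprintf("%.1f%%", 100 * x$sensitivity),
              if (is.na(x$specificity)) "NA" else sprintf("%.1f%%", 100 * x$specificity)))
  invisible(x)
}

#' Evaluate a classifier on a labeled test set
#'
#' Runs `predict()` on every pair and tallies the confusion matrix.
#' Deterministic given the model and data.
#'
#' @param model a `network_params` or `fusion_model` object.
#' @param test_set list of [labeled_image_pair()] objects.
#' @return list with `counts` ([confusion()]), `metrics` ([metrics()]) and
#'   `predictions` (data.frame: subject_id, truth, prediction, p_positive).
#' @export
evaluate <- function(model, test_set) {
  if (length(test_set) == 0L) stop("test set is empty")
  truth <- cohort_labels(test_set)
  pred <- predict(model, test_set)
  p_pos <- predict_proba(model, test_set)
  counts <- confusion(pred, truth)
  list(counts = counts, metrics = metrics(counts),
       predictions = data.frame(
         subject_id = vapply(test_set, function(p) p$subject_id, character(1)),
         truth = truth, prediction = pred, p_positive = p_pos,
         stringsAsFactors = FALSE))
}

# probability assigned to class 1 for each pair
predict_proba <- function(model, pairs) {
  probs <- if (inherits(model, "fusion_model")) {
    fusion_forward_batch(model, pairs)$probabilities
  } else {
    net_forward(model, images_to_batch(model, pairs))$probabilities
  }
  probs[2L, ]
}
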
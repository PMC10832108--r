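check_binary_labels <- function(labels) {
  if (!all(labels %in% c(0, 1))) rlang::abort("labels must be binary 0/1")
}

#' Area under the ROC curve
#'
#' Rank formulation: the probability that a uniformly chosen positive
#' outranks a uniformly chosen negative, with tied scores credited one
#' half. Equivalent to the Wilcoxon rank-sum statistic scaled to [0, 1].
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores, higher meaning more positive.
#' @return AUROC in [0, 1].
#' @examples
#' auroc(c(1, 0, 1, 0), c(0.8, 0.8, 0.6, 0.4))
#' @export
auroc <- function(labels, scores) {
  check_binary_labels(labels)
  stopifnot(length(labels) == length(scores))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    rlang::abort("AUROC is undefined without both classes")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve (average precision)
#'
#' Non-interpolated average precision: the mean over positives of the
#' precision at each positive's rank when examples are sorted by
#' decreasing score. Ties are broken stably by original position, which
#' makes the estimator deterministic.
#'
#' @inheritParams auroc
#' @return Average precision in (0, 1].
#' @examples
#' auprc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2))
#' @export
auprc <- function(labels, scores) {
  check_binary_labels(labels)
  stopifnot(length(labels) == length(scores))
  if (sum(labels == 1) == 0) {
    rlang::abort("AUPRC is undefined without positives")
  }
  ord <- order(-scores)
  sorted <- labels[ord]
  cum_pos <- cumsum(sorted)
  precision_at <- cum_pos / seq_along(sorted)
  mean(precision_at[sorted == 1])
}

#' Sensitivity and specificity at a decision threshold
#'
#' Scores at or above the threshold count as predicted positives (the
#' boundary is resolved towards positive). Sensitivity is TP / (TP + FN),
#' specificity TN / (TN + FP); each is NA when its class is absent.
#'
#' @inheritParams auroc
#' @param threshold Decision threshold (default 0.5).
#' @return Named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sens_spec <- function(labels, scores, threshold = 0.5) {
  check_binary_labels(labels)
  stopifnot(length(labels) == length(scores))
  pred <- as.integer(scores >= threshold)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  sens <- if (n_pos == 0) NA_real_ else sum(pred == 1 & labels == 1) / n_pos
  spec <- if (n_neg == 0) NA_real_ else sum(pred == 0 & labels == 0) / n_neg
  c(sensitivity = sens, specificity = spec)
}

#' Evaluate a model on a record split
#'
#' Scores every record in evaluation mode (dropout off) and reports the
#' four benchmark metrics alongside the class counts. Undefined metrics
#' (a split missing one class) are reported as NA rather than aborting the
#' report.
#'
#' @param model A `dti_model` or `dti_run` (the selected checkpoint is
#'   used).
#' @param records Interaction tibble with `label`.
#' @param cache A `teacher_cache` when the model has a teacher branch.
#' @param threshold Decision threshold for the confusion sub-metrics.
#' @param batch_size Scoring batch size.
#' @return A one-row tibble: `auroc`, `auprc`, `sensitivity`,
#'   `specificity`, `n_pos`, `n_neg`, `threshold`.
#' @export
evaluate_split <- function(model, records, cache = NULL, threshold = 0.5,
                           batch_size = 64L) {
  if (inherits(model, "dti_run")) model <- model$model
  if (nrow(records) == 0L) rlang::abort("records must be non-empty")
  scored <- predict(model, records, cache = cache, batch_size = batch_size)
  labels <- as.numeric(scored$label)
  scores <- scored$score
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  roc <- if (n_pos > 0 && n_neg > 0) auroc(labels, scores) else NA_real_
  prc <- if (n_pos > 0) auprc(labels, scores) else NA_real_
  ss <- sens_spec(labels, scores, threshold)
  tibble::tibble(
    auroc = roc, auprc = prc,
    sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]],
    n_pos = n_pos, n_neg = n_neg, threshold = threshold
  )
}

#' Evaluate the cold-split subsets of a bundle
#'
#' Applies [evaluate_split()] separately to the cold-drug, cold-target and
#' cold-binding subsets extracted from the bundle's test split.
#'
#' @param model A `dti_model` or `dti_run`.
#' @param bundle A `split_bundle`.
#' @param cache A `teacher_cache` when required.
#' @param ... Passed to [evaluate_split()].
#' @return A tibble with one row per non-empty cold subset and a `subset`
#'   column.
#' @export
evaluate_cold_splits <- function(model, bundle, cache = NULL, ...) {
  subsets <- extract_cold_subsets(bundle)
  rows <- purrr::imap(subsets, function(records, name) {
    if (nrow(records) == 0L) return(NULL)
    dplyr::mutate(evaluate_split(model, records, cache = cache, ...),
                  subset = name, n = nrow(records), .before = 1)
  })
  dplyr::bind_rows(rows)
}
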
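#' Per-class classification report
#'
#' Computes the confusion matrix and per-class precision, recall and F1
#' with their supports, plus accuracy, macro F1 (unweighted class mean) and
#' weighted F1 (support-weighted class mean). Undefined ratios (empty
#' denominator) are reported as 0.
#'
#' @param y_true,y_pred character/factor vectors of equal length.
#' @param labels label order for the report and confusion matrix; defaults
#'   to the sorted union of observed labels.
#' @return An object of class \code{"eval_report"}: list with
#'   \code{per_class} (data.frame), \code{accuracy}, \code{macro_f1},
#'   \code{weighted_f1} and \code{confusion} (true labels in rows).
#' @examples
#' classification_report(c("A", "A", "B"), c("A", "B", "B"))
#' @export
classification_report <- function(y_true, y_pred, labels = NULL) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (!length(y_true)) stop("empty input", call. = FALSE)
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length", call. = FALSE)
  }
  if (is.null(labels)) labels <- sort_labels(unique(c(y_true, y_pred)))
  extra <- setdiff(unique(c(y_true, y_pred)), labels)
  if (length(extra)) {
    stop(sprintf("labels outside the given label order: %s",
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  cm <- table(factor(y_true, levels = labels),
              factor(y_pred, levels = labels))
  tp <- diag(cm)
  support <- rowSums(cm)
  pred_n <- colSums(cm)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = labels, precision = as.numeric(precision),
                          recall = as.numeric(recall), f1 = as.numeric(f1),
                          support = as.integer(support))
  present <- support > 0
  structure(list(
    per_class = per_class,
    accuracy = sum(tp) / length(y_true),
    macro_f1 = mean(f1[present]),
    weighted_f1 = sum(f1 * support) / sum(support),
    confusion = unclass(cm)), class = "eval_report")
}

#' @export
print.eval_report <- function(x, digits = 3, ...) {
  cat(sprintf("Classification report (%d samples, %d classes)\n",
              sum(x$per_class$support), nrow(x$per_class)))
  pc <- x$per_class
  pc[2:4] <- lapply(pc[2:4], round, digits)
  print(pc, row.names = FALSE)
  cat(sprintf("accuracy %.*f | macro F1 %.*f | weighted F1 %.*f\n",
              digits, x$accuracy, digits, x$macro_f1, digits, x$weighted_f1))
  invisible(x)
}

#' Write an evaluation report
#'
#' Writes the per-class table and confusion matrix as TSV plus an
#' aggregate JSON next to them.
#'
#' @param report an \code{eval_report}.
#' @param prefix output path prefix; files \code{<prefix>_per_class.tsv},
#'   \code{<prefix>_confusion.tsv} and \code{<prefix>_summary.json} are
#'   written.
#' @return \code{prefix}, invisibly.
#' @export
write_eval_report <- function(report, prefix) {
  stopifnot(inherits(report, "eval_report"))
  utils::write.table(report$per_class, paste0(prefix, "_per_class.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- as.data.frame.matrix(report$confusion)
  cm <- cbind(true_label = rownames(cm), cm)
  utils::write.table(cm, paste0(prefix, "_confusion.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(accuracy = report$accuracy,
                            macro_f1 = report$macro_f1,
                            weighted_f1 = report$weighted_f1),
                       paste0(prefix, "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney identity: the probability that a
#' random positive outscores a random negative, counting ties as 1/2.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels binary labels: logical, 0/1, or a factor/character with
#'   exactly two values, in which case \code{positive} names the positive
#'   class.
#' @param positive positive class (defaults to \code{1}/\code{TRUE} or the
#'   alphabetically last level).
#' @return AUROC in \[0, 1\].
#' @examples
#' auroc(c(0.9, 0.8, 0.7, 0.1), c(1, 0, 1, 0))
#' @export
auroc <- function(scores, labels, positive = NULL) {
  stopifnot(length(scores) == length(labels))
  pos <- binarize_labels(labels, positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute AUROC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

binarize_labels <- function(labels, positive = NULL) {
  if (is.logical(labels)) return(labels)
  u <- sort_labels(unique(as.character(labels)))
  if (length(u) > 2L) {
    stop("labels must be binary", call. = FALSE)
  }
  if (is.null(positive)) {
    positive <- if (all(u %in% c("0", "1"))) "1" else u[length(u)]
  }
  as.character(labels) == as.character(positive)
}

#' ROC curve points
#'
#' Threshold sweep over the observed scores, for plotting or export.
#'
#' @inheritParams auroc
#' @return data.frame with columns \code{threshold}, \code{tpr},
#'   \code{fpr}.
#' @export
roc_points <- function(scores, labels, positive = NULL) {
  pos <- binarize_labels(labels, positive)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  data.frame(
    threshold = th,
    tpr = vapply(th, function(t) mean(scores[pos] >= t), numeric(1)),
    fpr = vapply(th, function(t) mean(scores[!pos] >= t), numeric(1)))
}

# One-vs-rest F1 for a single positive class from hard labels (internal;
# used by the stacked importance aggregation).
ovr_f1 <- function(y_true, y_pred, positive) {
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  fn <- sum(y_true == positive & y_pred != positive)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

# Metric dispatcher shared by importance and model selection.
score_fun <- function(metric, positive = NULL) {
  switch(metric,
    accuracy = function(y_true, y_pred) mean(y_true == y_pred),
    weighted_f1 = function(y_true, y_pred)
      classification_report(y_true, y_pred)$weighted_f1,
    macro_f1 = function(y_true, y_pred)
      classification_report(y_true, y_pred)$macro_f1,
    class_f1 = function(y_true, y_pred) ovr_f1(y_true, y_pred, positive),
    stop(sprintf("unknown metric '%s'", metric), call. = FALSE))
}
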
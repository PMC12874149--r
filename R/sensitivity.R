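#' Healthy-subsampling sensitivity analysis
#'
#' Evaluates the stability of the hierarchical model to the composition of
#' one class's training samples (typically the healthy controls). The
#' cohort is split once; a reference model is fitted on the full training
#' partition. Then, for each iteration, a fixed fraction of the target
#' class's training samples (\code{round(removal_fraction * n_target)}) is
#' removed uniformly at random, the model is retrained with unchanged
#' hyperparameters, and evaluated on the fixed test partition. For each
#' disease, the DeLong test compares the target-vs-disease
#' binary-restriction scores of the subsampled model against the reference
#' model on the same test samples.
#'
#' @param cohort an \code{\link{npx_cohort}}.
#' @param tax an \code{\link{taxonomy}}.
#' @param target_class class whose training samples are subsampled.
#' @param removal_fraction fraction removed per iteration, in (0, 1).
#' @param n_iter number of subsampling iterations.
#' @param train_fraction stratified split fraction (default 0.7).
#' @param first_stage,second_stage node specs (see \code{\link{two_stage}}).
#' @param oversample,smote_k oversampling settings passed to
#'   \code{\link{two_stage}}.
#' @param seed integer seed controlling the split, the model fits and the
#'   removals.
#' @return An object of class \code{"sensitivity_report"}: list with the
#'   reference \code{eval_report} (\code{reference}), \code{n_removed},
#'   and \code{iterations} — one element per iteration holding
#'   \code{removed} (sample ids), \code{accuracy}, \code{weighted_f1},
#'   \code{per_class_f1}, and \code{delong} (per-disease data.frame of AUCs
#'   and p values against the reference).
#' @export
sensitivity_analysis <- function(cohort, tax, target_class,
                                 removal_fraction = 0.25, n_iter = 50L,
                                 train_fraction = 0.7,
                                 first_stage = NULL, second_stage = NULL,
                                 oversample = TRUE, smote_k = 5L,
                                 seed = 1L) {
  stopifnot(inherits(cohort, "npx_cohort"), inherits(tax, "npx_taxonomy"))
  if (!(removal_fraction > 0 && removal_fraction < 1)) {
    fail_arg("removal_fraction", "must be in (0, 1)")
  }
  sp <- stratified_split(cohort, train_fraction, seed = seed)
  train <- sp$train; test <- sp$test
  target_idx <- which(train$labels == target_class)
  if (!length(target_idx)) {
    stop(sprintf("target class '%s' absent from the training partition",
                 target_class), call. = FALSE)
  }
  n_remove <- round(removal_fraction * length(target_idx))
  if (length(target_idx) - n_remove < 2L) {
    stop(sprintf(
      "removing %d of %d '%s' training samples would leave fewer than 2",
      n_remove, length(target_idx), target_class), call. = FALSE)
  }
  fit_and_eval <- function(tr) {
    m <- two_stage(tr, tax, first_stage = first_stage,
                   second_stage = second_stage, oversample = oversample,
                   smote_k = smote_k, seed = seed)
    pr <- predict_full(m, test)
    list(model = m, prob = pr,
         report = classification_report(
           test$labels, m$label_order[max.col(pr, ties.method = "first")],
           labels = m$label_order))
  }
  ref <- fit_and_eval(train)
  diseases <- setdiff(ref$model$label_order, target_class)
  binary_scores <- function(prob, disease) {
    rows <- which(test$labels %in% c(target_class, disease))
    if (!length(rows)) return(NULL)
    b <- restrict_binary(prob[rows, , drop = FALSE], target_class, disease)
    list(scores = b[, disease], labels = test$labels[rows])
  }
  iterations <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    removed <- if (n_remove > 0L) {
      with_seed(sub_seed(seed, 9000L + it),
                sample(target_idx, n_remove))
    } else integer()
    keep <- setdiff(seq_along(train$labels), removed)
    res <- fit_and_eval(cohort_subset(train, rows = keep))
    dl <- lapply(diseases, function(d) {
      bs_ref <- binary_scores(ref$prob, d)
      bs_it <- binary_scores(res$prob, d)
      if (is.null(bs_ref) ||
          length(unique(bs_ref$labels)) < 2L) {
        return(data.frame(disease = d, auc_ref = NA_real_,
                          auc_iter = NA_real_, p = NA_real_))
      }
      dt <- delong_test(bs_ref$scores, bs_it$scores, bs_ref$labels,
                        positive = d)
      data.frame(disease = d, auc_ref = dt$auc_1, auc_iter = dt$auc_2,
                 p = dt$p)
    })
    iterations[[it]] <- list(
      removed = rownames(train$npx)[removed],
      accuracy = res$report$accuracy,
      weighted_f1 = res$report$weighted_f1,
      per_class_f1 = stats::setNames(res$report$per_class$f1,
                                     res$report$per_class$class),
      delong = do.call(rbind, dl))
  }
  structure(list(reference = ref$report, target_class = target_class,
                 n_removed = n_remove, n_target_train = length(target_idx),
                 iterations = iterations),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  acc <- vapply(x$iterations, `[[`, numeric(1), "accuracy")
  wf1 <- vapply(x$iterations, `[[`, numeric(1), "weighted_f1")
  cat(sprintf(
    "Sensitivity analysis: %d iterations, %d of %d '%s' training samples removed each\n",
    length(x$iterations), x$n_removed, x$n_target_train, x$target_class))
  cat(sprintf("  reference: accuracy %.3f, weighted F1 %.3f\n",
              x$reference$accuracy, x$reference$weighted_f1))
  cat(sprintf("  subsampled accuracy: %.3f-%.3f | weighted F1: %.3f-%.3f\n",
              min(acc), max(acc), min(wf1), max(wf1)))
  sig <- vapply(x$iterations, function(it) {
    mean(it$delong$p < 0.05, na.rm = TRUE)
  }, numeric(1))
  cat(sprintf("  mean fraction of diseases with DeLong p < 0.05: %.2f\n",
              mean(sig, na.rm = TRUE)))
  invisible(x)
}
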
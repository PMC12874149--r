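#' Rank candidate node classifiers by cross-validated F1
#'
#' Stratified k-fold cross-validation over a cohort subset (typically the
#' training samples of one hierarchy node): each candidate is fitted on
#' k-1 folds and scored on the held-out fold by weighted F1; candidates are
#' ranked by the mean score over folds, descending, with ties broken by
#' their order in the candidate list. When oversampling is enabled,
#' borderline-SMOTE is applied to each fold's training part only — never to
#' the validation fold.
#'
#' @param X feature matrix (or \code{\link{npx_cohort}}).
#' @param y labels (ignored when \code{X} is a cohort).
#' @param candidates named list of \code{\link{node_spec}}s.
#' @param n_folds number of folds (>= 2); every class must have at least
#'   \code{n_folds} samples.
#' @param oversample apply borderline-SMOTE inside training folds.
#' @param smote_k neighbor count for the oversampler.
#' @param seed integer seed (fold assignment, oversampling, stochastic
#'   fits).
#' @return data.frame with columns \code{rank}, \code{candidate},
#'   \code{mean_cv_f1}, ordered by rank; attribute \code{"specs"} holds the
#'   specs in ranked order.
#' @export
select_classifier <- function(X, y = NULL, candidates, n_folds = 5L,
                              oversample = FALSE, smote_k = 5L, seed = 1L) {
  if (inherits(X, "npx_cohort")) {
    y <- X$labels
    X <- X$npx
  }
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  if (n_folds < 2L) fail_arg("n_folds", "must be >= 2")
  if (!length(candidates)) fail_arg("candidates", "must be non-empty")
  if (is.null(names(candidates))) {
    names(candidates) <- vapply(candidates, function(s) s$algorithm,
                                character(1))
  }
  counts <- table(y)
  small <- names(counts)[counts < n_folds]
  if (length(small)) {
    stop(sprintf("class(es) with fewer than %d samples: %s",
                 n_folds, paste(small, collapse = ", ")), call. = FALSE)
  }
  folds <- with_seed(seed, {
    f <- integer(length(y))
    for (cls in names(counts)) {
      idx <- which(y == cls)
      f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    f
  })
  scores <- vapply(seq_along(candidates), function(ci) {
    spec <- candidates[[ci]]
    fold_f1 <- vapply(seq_len(n_folds), function(k) {
      tr <- folds != k
      Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]
      if (oversample && length(unique(ytr)) >= 2L) {
        aug <- borderline_smote(Xtr, ytr, k = smote_k,
                                seed = sub_seed(seed, 1000L * ci + k))
        Xtr <- aug$X; ytr <- aug$y
      }
      fit <- fit_node(spec, Xtr, ytr, seed = sub_seed(seed, 2000L * ci + k))
      pr <- node_probs(fit, X[!tr, , drop = FALSE])
      pred <- fit$levels[max.col(pr, ties.method = "first")]
      classification_report(y[!tr], pred,
                            labels = sort_labels(unique(y)))$weighted_f1
    }, numeric(1))
    mean(fold_f1)
  }, numeric(1))
  ord <- order(-scores, seq_along(scores))
  out <- data.frame(rank = seq_along(ord),
                    candidate = names(candidates)[ord],
                    mean_cv_f1 = scores[ord])
  attr(out, "specs") <- candidates[ord]
  out
}
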
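#' Permutation feature importance
#'
#' Importance of feature \eqn{i} is the expected drop in a test-set score
#' when column \eqn{i} is randomly permuted:
#' \deqn{\frac{1}{|\Sigma|}\sum_{\sigma_i}
#'   [s(F(X_{test}), y) - s(F(\sigma_i(X_{test})), y)],}
#' approximated by \code{n_perm} random permutations (the exact average over
#' all \eqn{n!} orderings is infeasible beyond tiny test sets). A constant
#' column scores exactly 0 since permuting it is a no-op.
#'
#' @param model a fitted \code{\link{two_stage}} model, or any function
#'   mapping a feature matrix to predicted labels.
#' @param X test feature matrix (or \code{\link{npx_cohort}}).
#' @param y true labels (ignored when \code{X} is a cohort).
#' @param metric \code{"weighted_f1"} (default), \code{"accuracy"},
#'   \code{"macro_f1"}, or \code{"class_f1"} (one-vs-rest F1 for
#'   \code{positive}).
#' @param n_perm number of random permutations per feature (default 1000).
#' @param seed integer seed; results are deterministic given the seed.
#' @param exact enumerate all \eqn{n!} column orderings instead of sampling
#'   (test sets of at most 7 samples).
#' @param features columns to evaluate (default all).
#' @param positive positive class for \code{metric = "class_f1"}.
#' @return Named numeric vector of mean score drops, one per feature.
#' @export
permutation_importance <- function(model, X, y = NULL,
                                   metric = "weighted_f1", n_perm = 1000L,
                                   seed = 1L, exact = FALSE,
                                   features = NULL, positive = NULL) {
  if (inherits(X, "npx_cohort")) {
    y <- X$labels
    X <- X$npx
  }
  X <- as.matrix(X)
  y <- as.character(y)
  if (!nrow(X)) stop("empty test set", call. = FALSE)
  stopifnot(nrow(X) == length(y))
  if (!exact && n_perm < 1L) fail_arg("n_perm", "must be >= 1")
  predict_labels <- if (is.function(model)) model else {
    function(M) predict(model, M)
  }
  s <- score_fun(metric, positive)
  baseline <- s(y, predict_labels(X))
  features <- features %||% seq_len(ncol(X))
  perms <- if (exact) {
    if (nrow(X) > 7L) {
      stop("exact enumeration is limited to test sets of <= 7 samples",
           call. = FALSE)
    }
    all_permutations(nrow(X))
  } else {
    with_seed(seed, lapply(seq_len(n_perm * length(features)),
                           function(i) sample.int(nrow(X))))
  }
  out <- numeric(length(features))
  for (fi in seq_along(features)) {
    col <- features[fi]
    if (length(unique(X[, col])) == 1L) {
      out[fi] <- 0  # permutation is a no-op on a constant column
      next
    }
    idx_set <- if (exact) perms else {
      perms[((fi - 1L) * n_perm + 1L):(fi * n_perm)]
    }
    drops <- vapply(idx_set, function(ord) {
      Xp <- X
      Xp[, col] <- X[ord, col]
      baseline - s(y, predict_labels(Xp))
    }, numeric(1))
    out[fi] <- mean(drops)
  }
  names(out) <- colnames(X)[features] %||% as.character(features)
  out
}

# All permutations of 1..n as a list (n <= 7).
all_permutations <- function(n) {
  perm_of <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perm_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  perm_of(seq_len(n))
}

#' Cross-disease stacked permutation importance
#'
#' Ranks proteins by their contribution across diseases: for each disease
#' the one-vs-rest F1 drop under column permutation is the protein's
#' contribution to that disease; the occurrence count is the number of
#' diseases with a strictly positive contribution, and the stacked score is
#' the sum of the positive contributions. Proteins are ranked by occurrence
#' (descending), ties by stacked score (descending), then by column order.
#' Each column permutation is predicted once and scored against every
#' disease, so the cost is one model evaluation per permutation per
#' feature.
#'
#' @inheritParams permutation_importance
#' @param diseases classes to score one-vs-rest (default: all labels the
#'   model emits).
#' @return An object of class \code{"importance_table"}: data.frame with
#'   \code{protein}, one contribution column per disease,
#'   \code{occurrence}, \code{stacked_score}, \code{rank}, ordered by rank.
#' @seealso \code{\link{top_k}}, \code{\link{write_importance_table}}
#' @export
stacked_importance <- function(model, X, y = NULL, diseases = NULL,
                               n_perm = 1000L, seed = 1L, exact = FALSE,
                               features = NULL) {
  if (inherits(X, "npx_cohort")) {
    y <- X$labels
    X <- X$npx
  }
  X <- as.matrix(X)
  y <- as.character(y)
  if (!nrow(X)) stop("empty test set", call. = FALSE)
  predict_labels <- if (is.function(model)) model else {
    function(M) predict(model, M)
  }
  if (is.null(diseases)) {
    diseases <- if (inherits(model, "two_stage")) model$label_order
                else sort_labels(unique(y))
  }
  features <- features %||% seq_len(ncol(X))
  base_pred <- predict_labels(X)
  base_f1 <- vapply(diseases, function(d) ovr_f1(y, base_pred, d), numeric(1))
  perms <- if (exact) {
    if (nrow(X) > 7L) {
      stop("exact enumeration is limited to test sets of <= 7 samples",
           call. = FALSE)
    }
    all_permutations(nrow(X))
  } else {
    with_seed(seed, lapply(seq_len(n_perm * length(features)),
                           function(i) sample.int(nrow(X))))
  }
  contrib <- matrix(0, length(features), length(diseases),
                    dimnames = list(NULL, diseases))
  for (fi in seq_along(features)) {
    col <- features[fi]
    if (length(unique(X[, col])) == 1L) next
    idx_set <- if (exact) perms else {
      perms[((fi - 1L) * n_perm + 1L):(fi * n_perm)]
    }
    acc <- numeric(length(diseases))
    for (ord in idx_set) {
      Xp <- X
      Xp[, col] <- X[ord, col]
      pred <- predict_labels(Xp)
      acc <- acc + (base_f1 -
        vapply(diseases, function(d) ovr_f1(y, pred, d), numeric(1)))
    }
    contrib[fi, ] <- acc / length(idx_set)
  }
  prot <- colnames(X)[features] %||% as.character(features)
  occurrence <- rowSums(contrib > 0)
  stacked <- rowSums(contrib * (contrib > 0))
  ord <- order(-occurrence, -stacked, seq_along(occurrence))
  out <- data.frame(protein = prot, contrib, check.names = FALSE)
  out$occurrence <- as.integer(occurrence)
  out$stacked_score <- stacked
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}

#' Top-ranked proteins of an importance table
#'
#' @param table an \code{\link{stacked_importance}} result.
#' @param k number of proteins to return (1 <= k <= number of rows).
#' @return Character vector of the first \code{k} protein names under the
#'   table's ranking; feeds \code{\link{restrict_to_features}} directly.
#' @export
top_k <- function(table, k) {
  stopifnot(inherits(table, "importance_table"))
  if (k <= 0L) fail_arg("k", "must be >= 1")
  if (k > nrow(table)) {
    fail_arg("k", sprintf("exceeds the number of features (%d)", nrow(table)))
  }
  table$protein[seq_len(k)]
}

#' @export
print.importance_table <- function(x, n = 10L, ...) {
  cat(sprintf("Stacked protein importance: %d proteins x %d diseases\n",
              nrow(x), sum(!names(x) %in%
                           c("protein", "occurrence", "stacked_score",
                             "rank"))))
  slim <- as.data.frame(x)[seq_len(min(n, nrow(x))),
                           c("rank", "protein", "occurrence",
                             "stacked_score")]
  slim$stacked_score <- round(slim$stacked_score, 4)
  print(slim, row.names = FALSE)
  if (nrow(x) > n) cat(sprintf("... %d more\n", nrow(x) - n))
  invisible(x)
}

#' @export
plot.importance_table <- function(x, n = 20L, ...) {
  disease_cols <- setdiff(names(x), c("protein", "occurrence",
                                      "stacked_score", "rank"))
  top <- utils::head(x, n)
  m <- t(as.matrix(top[, disease_cols, drop = FALSE]))
  m[m < 0] <- 0
  graphics::barplot(m, names.arg = top$protein, las = 2,
                    col = grDevices::hcl.colors(nrow(m), "Spectral"),
                    ylab = "stacked positive F1 contribution", ...)
  invisible(x)
}

#' Write an importance table as TSV
#'
#' @param table an \code{\link{stacked_importance}} result.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_importance_table <- function(table, path) {
  stopifnot(inherits(table, "importance_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
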
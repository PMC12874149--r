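#' Stratified train/test split
#'
#' Splits a cohort class-by-class: each class contributes
#' \code{ceiling(train_fraction * n_class)} samples to the training
#' partition (so a 137-sample class at fraction 0.7 puts 96 samples in
#' training), the rest to testing. Partitions are disjoint and exhaustive
#' and deterministic given the seed.
#'
#' @param cohort an \code{\link{npx_cohort}}.
#' @param train_fraction fraction in (0, 1); default 0.7.
#' @param seed integer seed.
#' @return List with elements \code{train} and \code{test}, both
#'   \code{npx_cohort}s.
#' @export
stratified_split <- function(cohort, train_fraction = 0.7, seed = 1L) {
  stopifnot(inherits(cohort, "npx_cohort"))
  if (!(train_fraction > 0 && train_fraction < 1)) {
    fail_arg("train_fraction", "must be in (0, 1)")
  }
  counts <- table(cohort$labels)
  singletons <- names(counts)[counts < 2L]
  if (length(singletons)) {
    stop(sprintf(
      "class(es) with a single sample cannot be split: %s; merge them into a broader class or exclude them",
      paste(singletons, collapse = ", ")), call. = FALSE)
  }
  train_idx <- with_seed(seed, {
    unlist(lapply(names(counts), function(cls) {
      idx <- which(cohort$labels == cls)
      n_train <- ceiling(train_fraction * length(idx))
      sort(sample(idx, n_train))
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  list(train = cohort_subset(cohort, rows = train_idx),
       test = cohort_subset(cohort, rows = setdiff(seq_along(cohort$labels),
                                                   train_idx)))
}

#' Default node specs mirroring the study design
#'
#' First stage: perceptron. Second stage, matched on the category name:
#' extremely randomized trees for blood diseases, hinge-SGD linear for
#' psychiatric, ridge for metabolic, logistic regression for tumors;
#' logistic regression for any unrecognized category name.
#'
#' @param tax an \code{\link{taxonomy}}.
#' @return List with elements \code{first_stage} (a
#'   \code{\link{node_spec}}) and \code{second_stage} (named list of specs,
#'   one per category).
#' @export
default_node_specs <- function(tax) {
  stopifnot(inherits(tax, "npx_taxonomy"))
  pick <- function(nm) {
    l <- tolower(nm)
    if (grepl("blood|h(a)?ema", l)) node_spec("extratrees")
    else if (grepl("psych", l)) node_spec("sgd")
    else if (grepl("metab", l)) node_spec("ridge")
    else if (grepl("tumou?r|cancer|onco", l)) node_spec("logistic")
    else node_spec("logistic")
  }
  list(first_stage = node_spec("perceptron"),
       second_stage = stats::setNames(
         lapply(names(tax$categories), pick), names(tax$categories)))
}

#' Fit a two-stage hierarchical classifier
#'
#' Fits the knowledge-guided hierarchical model: a first-stage classifier
#' over the taxonomy's first-stage classes (category names plus terminal
#' labels), trained on \code{(x, category(y))}, and one second-stage
#' classifier per non-terminal category, trained only on the samples of
#' that category. A category with a single phenotype present is fitted as
#' a pass-through node. When oversampling is enabled, borderline-SMOTE is
#' applied independently inside each node's training data (never to
#' evaluation data).
#'
#' The fitted model emits, for any sample, a probability vector over all
#' phenotypes via the product mixture
#' \deqn{P(X) = \sum_j P_f(j | X) \, P_{g_j}(\cdot | X),}
#' where \eqn{P_f} is the first-stage posterior and \eqn{P_{g_j}} the
#' second-stage posterior within category \eqn{j}; terminal classes
#' contribute their first-stage probability directly. With a one-hot first
#' stage this reduces to hard routing: classify the category, then classify
#' within it.
#'
#' @param cohort training \code{\link{npx_cohort}}.
#' @param tax an \code{\link{taxonomy}} covering every cohort label.
#' @param first_stage \code{\link{node_spec}} for the category classifier
#'   (default per \code{\link{default_node_specs}}).
#' @param second_stage named list of \code{node_spec}s keyed by category
#'   name (defaults per \code{\link{default_node_specs}}; missing entries
#'   fall back to their default).
#' @param oversample logical: apply borderline-SMOTE inside each node's
#'   training data.
#' @param smote_k neighbor count for the oversampler.
#' @param seed integer seed controlling oversampling and any stochastic
#'   node training.
#' @return An object of class \code{"two_stage"} with \code{print},
#'   \code{summary} and \code{predict} methods.
#' @seealso \code{\link{predict.two_stage}}, \code{\link{restrict_binary}},
#'   \code{\link{restrict_to_features}}
#' @export
two_stage <- function(cohort, tax, first_stage = NULL, second_stage = NULL,
                      oversample = TRUE, smote_k = 5L, seed = 1L) {
  stopifnot(inherits(cohort, "npx_cohort"), inherits(tax, "npx_taxonomy"))
  unmapped <- validate_cohort_against_taxonomy(cohort, tax)
  if (length(unmapped)) {
    stop(sprintf("cohort labels not covered by the taxonomy: %s",
                 paste(unmapped, collapse = ", ")), call. = FALSE)
  }
  if (anyNA(cohort$npx)) {
    stop("training cohort contains missing NPX values", call. = FALSE)
  }
  defaults <- default_node_specs(tax)
  first_stage <- first_stage %||% defaults$first_stage
  ss_specs <- defaults$second_stage
  for (nm in names(second_stage)) ss_specs[[nm]] <- second_stage[[nm]]

  present <- unique(cohort$labels)
  lab_order <- intersect(label_order(tax), present)
  cats <- category_of(tax, cohort$labels)
  fs_classes <- intersect(first_stage_classes(tax), unique(cats))

  maybe_smote <- function(X, y, stream) {
    if (!oversample || length(unique(y)) < 2L) {
      return(list(X = X, y = y))
    }
    aug <- borderline_smote(X, y, k = smote_k,
                            seed = sub_seed(seed, stream))
    list(X = aug$X, y = aug$y)
  }

  fs_data <- maybe_smote(cohort$npx, cats, stream = 1L)
  f_fit <- fit_node(first_stage, fs_data$X, fs_data$y,
                    seed = sub_seed(seed, 100L))

  g_fits <- list()
  for (j in seq_along(tax$categories)) {
    nm <- names(tax$categories)[j]
    if (!nm %in% fs_classes) next
    rows <- which(cats == nm)
    members <- intersect(tax$categories[[nm]], unique(cohort$labels[rows]))
    if (length(members) == 1L) {
      message(sprintf(
        "category '%s' has a single phenotype (%s); fitted as a pass-through node",
        nm, members))
      g_fits[[nm]] <- list(passthrough = TRUE, label = members)
      next
    }
    nd <- maybe_smote(cohort$npx[rows, , drop = FALSE],
                      cohort$labels[rows], stream = 1L + j)
    g_fits[[nm]] <- list(
      passthrough = FALSE,
      node = fit_node(ss_specs[[nm]], nd$X, nd$y,
                      seed = sub_seed(seed, 100L + j)),
      members = members)
  }

  structure(list(
    taxonomy = tax,
    first_stage = f_fit,
    second_stage = g_fits,
    first_classes = fs_classes,
    label_order = lab_order,
    specs = list(first_stage = first_stage, second_stage = ss_specs),
    oversample = oversample, smote_k = smote_k, seed = seed,
    n_features = ncol(cohort$npx),
    feature_names = colnames(cohort$npx)), class = "two_stage")
}

#' Full-resolution class probabilities of the hierarchical model
#'
#' Evaluates the two-stage product mixture for every sample: the entry for
#' phenotype \eqn{\ell} in category \eqn{j} is
#' \eqn{P_f(j | x) P_{g_j}(\ell | x)}; the entry for a terminal phenotype
#' is its first-stage probability. Every row sums to 1.
#'
#' @param model a fitted \code{\link{two_stage}} model.
#' @param X feature matrix (or \code{npx_cohort}) with the training feature
#'   count.
#' @return Matrix samples x phenotypes, columns in the model's fixed label
#'   order.
#' @export
predict_full <- function(model, X) {
  stopifnot(inherits(model, "two_stage"))
  if (inherits(X, "npx_cohort")) X <- X$npx
  X <- as.matrix(X)
  if (ncol(X) != model$n_features) {
    stop(sprintf("feature mismatch: model trained on %d features, got %d",
                 model$n_features, ncol(X)), call. = FALSE)
  }
  pf <- node_probs(model$first_stage, X)
  out <- matrix(0, nrow(X), length(model$label_order),
                dimnames = list(rownames(X), model$label_order))
  for (cls in model$first_classes) {
    if (cls %in% names(model$second_stage)) {
      g <- model$second_stage[[cls]]
      if (isTRUE(g$passthrough)) {
        out[, g$label] <- pf[, cls]
      } else {
        pg <- node_probs(g$node, X)
        for (m in g$members) {
          out[, m] <- pf[, cls] * pg[, m]
        }
      }
    } else {
      # terminal first-stage class: the label is its own path
      out[, cls] <- pf[, cls]
    }
  }
  out
}

#' Predict phenotypes or probabilities
#'
#' @param object a fitted \code{\link{two_stage}} model.
#' @param newdata feature matrix or \code{\link{npx_cohort}}.
#' @param type \code{"class"} for hard labels (argmax of the full
#'   probability vector, ties broken by the model's fixed label order) or
#'   \code{"prob"} for the full probability matrix.
#' @param ... unused.
#' @return Character vector of labels, or the probability matrix.
#' @export
predict.two_stage <- function(object, newdata, type = c("class", "prob"),
                              ...) {
  type <- match.arg(type)
  pr <- predict_full(object, newdata)
  if (type == "prob") return(pr)
  object$label_order[max.col(pr, ties.method = "first")]
}

#' @export
print.two_stage <- function(x, ...) {
  cat(sprintf(
    "Two-stage hierarchical classifier: %d first-stage class(es), %d phenotype(s)\n",
    length(x$first_classes), length(x$label_order)))
  cat(sprintf("  first stage: %s (%s)\n", x$first_stage$spec$algorithm,
              x$first_stage$spec$prob_rule))
  for (nm in names(x$second_stage)) {
    g <- x$second_stage[[nm]]
    if (isTRUE(g$passthrough)) {
      cat(sprintf("  %s: pass-through -> %s\n", nm, g$label))
    } else {
      cat(sprintf("  %s: %s over {%s}\n", nm, g$node$spec$algorithm,
                  paste(g$members, collapse = ", ")))
    }
  }
  cat(sprintf("  oversampling: %s | features: %d | seed: %d\n",
              if (x$oversample) sprintf("borderline-SMOTE (k=%d)", x$smote_k)
              else "off", x$n_features, x$seed))
  invisible(x)
}

#' @export
summary.two_stage <- function(object, ...) {
  print(object)
  cat("\nLabel order:\n  ")
  cat(paste(object$label_order, collapse = ", "), "\n")
  invisible(object)
}

#' Binary restriction of a multiclass probability matrix
#'
#' Extracts two columns of a full probability matrix and renormalizes each
#' row to sum to one — the evaluation device used to score disease vs
#' healthy discrimination without retraining. Rows where both entries are
#' zero are set to (0.5, 0.5) with a warning.
#'
#' @param prob_matrix matrix from \code{\link{predict_full}}.
#' @param class_a,class_b column names to restrict to.
#' @return Matrix samples x 2 with columns \code{class_a}, \code{class_b};
#'   rows sum to 1.
#' @export
restrict_binary <- function(prob_matrix, class_a, class_b) {
  missing_cls <- setdiff(c(class_a, class_b), colnames(prob_matrix))
  if (length(missing_cls)) {
    stop(sprintf("class(es) not in the probability matrix: %s",
                 paste(missing_cls, collapse = ", ")), call. = FALSE)
  }
  two <- prob_matrix[, c(class_a, class_b), drop = FALSE]
  tot <- rowSums(two)
  zero <- tot == 0
  if (any(zero)) {
    warning(sprintf(
      "%d row(s) with zero probability on both classes set to (0.5, 0.5)",
      sum(zero)), call. = FALSE)
    two[zero, ] <- 0.5
    tot[zero] <- 1
  }
  two / tot
}

#' Refit the hierarchy on a feature subset
#'
#' Identical architecture and training protocol, fitted on the given
#' protein columns only — the device used to evaluate performance on
#' top-ranked protein panels.
#'
#' @inheritParams two_stage
#' @param features character vector of protein names (or column indices).
#' @return A \code{\link{two_stage}} model trained on the column subset.
#' @export
restrict_to_features <- function(cohort, tax, features, first_stage = NULL,
                                 second_stage = NULL, oversample = TRUE,
                                 smote_k = 5L, seed = 1L) {
  stopifnot(inherits(cohort, "npx_cohort"))
  if (!length(features)) fail_arg("features", "must be non-empty")
  if (is.character(features)) {
    unknown <- setdiff(features, colnames(cohort$npx))
    if (length(unknown)) {
      stop(sprintf("unknown feature(s): %s", paste(unknown, collapse = ", ")),
           call. = FALSE)
    }
  }
  two_stage(cohort_subset(cohort, cols = features), tax,
            first_stage = first_stage, second_stage = second_stage,
            oversample = oversample, smote_k = smote_k, seed = seed)
}
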
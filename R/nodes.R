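#' Specify a node classifier
#'
#' Every node of the two-stage hierarchy (the first-stage category
#' classifier and each within-category classifier) is described by a spec:
#' an algorithm, its hyperparameters, and a score-to-probability rule. The
#' supported algorithms mirror the linear / tree families commonly used on
#' NPX feature tables:
#' \describe{
#'   \item{\code{"logistic"}}{multinomial logistic regression
#'     (\code{nnet::multinom}); native probabilities.}
#'   \item{\code{"ridge"}}{ridge classifier: one-vs-rest penalized least
#'     squares on +/-1 class indicators; decision scores, softmax by
#'     default. Hyperparameter \code{alpha} (L2 penalty, default 1).}
#'   \item{\code{"perceptron"}}{averaged multiclass perceptron; decision
#'     scores. Hyperparameter \code{epochs} (default 50).}
#'   \item{\code{"sgd"}}{one-vs-rest linear classifier trained by
#'     stochastic gradient descent on the hinge loss with L2 penalty;
#'     decision scores. Hyperparameters \code{alpha} (default 1e-4),
#'     \code{epochs} (default 20), \code{eta0} (default 0.1).}
#'   \item{\code{"extratrees"}}{extremely randomized trees
#'     (\code{ranger} with \code{splitrule = "extratrees"}); native
#'     probabilities. Hyperparameter \code{num.trees} (default 100).}
#'   \item{\code{"rf"}}{random forest (\code{ranger}); native
#'     probabilities.}
#'   \item{\code{"dummy"}}{class-prior baseline; native probabilities.}
#' }
#'
#' Linear algorithms standardize features internally using training-set
#' statistics. The probability rule maps decision scores to a per-class
#' probability vector: \code{"native"} (the algorithm's own posterior),
#' \code{"softmax"} over decision scores, or \code{"onehot"} on the argmax
#' (hard routing).
#'
#' @param algorithm one of the names above.
#' @param prob_rule \code{"native"}, \code{"softmax"} or \code{"onehot"};
#'   default \code{"native"} for probabilistic algorithms, \code{"softmax"}
#'   for score-based ones.
#' @param ... hyperparameters (see above).
#' @return An object of class \code{"node_spec"}.
#' @examples
#' node_spec("perceptron")
#' node_spec("ridge", alpha = 0.5, prob_rule = "onehot")
#' @export
node_spec <- function(algorithm = c("logistic", "ridge", "perceptron",
                                    "sgd", "extratrees", "rf", "dummy"),
                      prob_rule = NULL, ...) {
  algorithm <- match.arg(algorithm)
  default_rule <- if (algorithm %in% c("logistic", "extratrees", "rf", "dummy"))
    "native" else "softmax"
  prob_rule <- match.arg(prob_rule %||% default_rule,
                         c("native", "softmax", "onehot"))
  if (prob_rule == "native" &&
      algorithm %in% c("ridge", "perceptron", "sgd")) {
    fail_arg("prob_rule",
             sprintf("'%s' emits decision scores only; use softmax or onehot",
                     algorithm))
  }
  structure(list(algorithm = algorithm, prob_rule = prob_rule,
                 hyper = list(...)),
            class = "node_spec")
}

#' @export
print.node_spec <- function(x, ...) {
  hp <- if (length(x$hyper)) {
    paste(sprintf("%s=%s", names(x$hyper), unlist(x$hyper)), collapse = ", ")
  } else "defaults"
  cat(sprintf("node classifier: %s (%s; prob rule: %s)\n",
              x$algorithm, hp, x$prob_rule))
  invisible(x)
}

hyper_or <- function(spec, name, default) spec$hyper[[name]] %||% default

# Standardization used by the linear algorithms.
fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}
apply_scaler <- function(scaler, X) {
  sweep(sweep(X, 2L, scaler$center), 2L, scaler$scale, "/")
}

#' Fit a node classifier
#'
#' @param spec a \code{\link{node_spec}}.
#' @param X training feature matrix.
#' @param y training labels (>= 2 classes except for \code{"dummy"}).
#' @param seed integer seed for the algorithm's internal randomness.
#' @return A fitted node of class \code{"node_fit"}; use
#'   \code{\link{node_scores}} / \code{\link{node_probs}} on it.
#' @keywords internal
#' @export
fit_node <- function(spec, X, y, seed = 1L) {
  stopifnot(inherits(spec, "node_spec"))
  X <- as.matrix(X)
  y <- as.character(y)
  if (anyNA(X)) stop("NPX matrix contains missing values; impute or drop",
                     call. = FALSE)
  lv <- sort_labels(unique(y))
  if (length(lv) < 2L && spec$algorithm != "dummy") {
    stop(sprintf("node needs >= 2 classes, got: %s", paste(lv, collapse = ", ")),
         call. = FALSE)
  }
  fit <- with_seed(seed, switch(
    spec$algorithm,
    logistic = {
      df <- data.frame(.y = factor(y, levels = lv), X, check.names = FALSE)
      utils::capture.output(m <- nnet::multinom(
        .y ~ ., data = df, trace = FALSE,
        maxit = hyper_or(spec, "maxit", 100L),
        MaxNWts = 10L * (ncol(X) + 1L) * length(lv) + 1000L))
      list(model = m, cols = colnames(X))
    },
    ridge = fit_ridge_node(X, y, lv, alpha = hyper_or(spec, "alpha", 1)),
    perceptron = fit_perceptron_node(X, y, lv,
                                     epochs = hyper_or(spec, "epochs", 50L)),
    sgd = fit_sgd_node(X, y, lv,
                       alpha = hyper_or(spec, "alpha", 1e-4),
                       epochs = hyper_or(spec, "epochs", 20L),
                       eta0 = hyper_or(spec, "eta0", 0.1)),
    extratrees = list(model = ranger::ranger(
      x = X, y = factor(y, levels = lv), probability = TRUE,
      splitrule = "extratrees", num.random.splits = 1L,
      replace = FALSE, sample.fraction = 1,
      num.trees = hyper_or(spec, "num.trees", 100L),
      seed = seed, num.threads = 1L)),
    rf = list(model = ranger::ranger(
      x = X, y = factor(y, levels = lv), probability = TRUE,
      num.trees = hyper_or(spec, "num.trees", 100L),
      seed = seed, num.threads = 1L)),
    dummy = list(prior = as.numeric(table(factor(y, levels = lv))) / length(y))
  ))
  structure(list(spec = spec, levels = lv, fit = fit,
                 n_features = ncol(X), feature_names = colnames(X)),
            class = "node_fit")
}

# Ridge classifier: one-vs-rest least squares on +/-1 indicators with L2
# penalty on the (standardized) slopes; scores are the linear predictors.
fit_ridge_node <- function(X, y, lv, alpha) {
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  Y <- sapply(lv, function(l) ifelse(y == l, 1, -1))
  ym <- colMeans(Y)
  Yc <- sweep(Y, 2L, ym)
  XtX <- crossprod(Xs) + diag(alpha, ncol(Xs))
  W <- solve(XtX, crossprod(Xs, Yc))
  list(scaler = scaler, W = W, b = ym)
}

# Averaged multiclass perceptron on standardized features.
fit_perceptron_node <- function(X, y, lv, epochs) {
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  yi <- match(y, lv)
  p <- ncol(Xs); C <- length(lv); n <- nrow(Xs)
  W <- matrix(0, p, C); b <- numeric(C)
  Wsum <- matrix(0, p, C); bsum <- numeric(C)
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      s <- drop(Xs[i, ] %*% W) + b
      pred <- which.max(s)
      truth <- yi[i]
      if (pred != truth) {
        W[, truth] <- W[, truth] + Xs[i, ]; b[truth] <- b[truth] + 1
        W[, pred] <- W[, pred] - Xs[i, ]; b[pred] <- b[pred] - 1
      }
      Wsum <- Wsum + W; bsum <- bsum + b
    }
  }
  list(scaler = scaler, W = Wsum / (n * epochs), b = bsum / (n * epochs))
}

# One-vs-rest hinge-loss SGD with L2 penalty, averaged iterates.
fit_sgd_node <- function(X, y, lv, alpha, epochs, eta0) {
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  p <- ncol(Xs); n <- nrow(Xs)
  W <- matrix(0, p, length(lv)); b <- numeric(length(lv))
  for (ci in seq_along(lv)) {
    t_sgn <- ifelse(y == lv[ci], 1, -1)
    w <- numeric(p); bb <- 0
    wsum <- numeric(p); bsum <- 0; tcount <- 0
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        tcount <- tcount + 1
        eta <- eta0 / (1 + alpha * eta0 * tcount)
        margin <- t_sgn[i] * (sum(Xs[i, ] * w) + bb)
        w <- w * (1 - eta * alpha)
        if (margin < 1) {
          w <- w + eta * t_sgn[i] * Xs[i, ]
          bb <- bb + eta * t_sgn[i]
        }
        wsum <- wsum + w; bsum <- bsum + bb
      }
    }
    W[, ci] <- wsum / tcount; b[ci] <- bsum / tcount
  }
  list(scaler = scaler, W = W, b = b)
}

#' Decision scores of a fitted node
#'
#' @param node a \code{"node_fit"}.
#' @param X feature matrix with the training feature count.
#' @return Matrix samples x classes of decision scores (probabilities for
#'   native-probability algorithms).
#' @keywords internal
#' @export
node_scores <- function(node, X) {
  X <- as.matrix(X)
  if (ncol(X) != node$n_features) {
    stop(sprintf("feature mismatch: model trained on %d features, got %d",
                 node$n_features, ncol(X)), call. = FALSE)
  }
  lv <- node$levels
  alg <- node$spec$algorithm
  if (alg %in% c("ridge", "perceptron", "sgd")) {
    Xs <- apply_scaler(node$fit$scaler, X)
    s <- Xs %*% node$fit$W
    s <- sweep(s, 2L, node$fit$b, "+")
    colnames(s) <- lv
    return(s)
  }
  if (alg == "logistic") {
    nd <- as.data.frame(X)
    names(nd) <- node$fit$cols
    pr <- stats::predict(node$fit$model, newdata = nd, type = "probs")
    if (length(lv) == 2L) {
      pr <- cbind(1 - pr, pr)
    }
    pr <- matrix(pr, nrow = nrow(X))
    colnames(pr) <- lv
    return(pr)
  }
  if (alg %in% c("extratrees", "rf")) {
    pr <- stats::predict(node$fit$model, data = X,
                         num.threads = 1L)$predictions
    return(pr[, lv, drop = FALSE])
  }
  if (alg == "dummy") {
    pr <- matrix(node$fit$prior, nrow(X), length(lv), byrow = TRUE)
    colnames(pr) <- lv
    return(pr)
  }
  stop("unknown algorithm")
}

#' Per-class probabilities of a fitted node
#'
#' Applies the node's configured score-to-probability rule to its decision
#' scores.
#'
#' @inheritParams node_scores
#' @return Matrix samples x classes; rows sum to 1.
#' @keywords internal
#' @export
node_probs <- function(node, X) {
  s <- node_scores(node, X)
  out <- switch(node$spec$prob_rule,
    native = {
      # native scores are probabilities already; renormalize for safety
      s / pmax(rowSums(s), .Machine$double.eps)
    },
    softmax = if (node$spec$algorithm %in%
                  c("logistic", "extratrees", "rf", "dummy")) {
      # probabilistic scores: softmax would flatten them; use log-odds scale
      softmax_rows(log(pmax(s, 1e-12)))
    } else {
      softmax_rows(s)
    },
    onehot = {
      hard <- max.col(s, ties.method = "first")
      m <- matrix(0, nrow(s), ncol(s), dimnames = dimnames(s))
      m[cbind(seq_len(nrow(s)), hard)] <- 1
      m
    })
  colnames(out) <- node$levels
  out
}
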
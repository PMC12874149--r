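#' DeLong test for two correlated ROC curves
#'
#' Nonparametric test of the null hypothesis that two AUCs computed from
#' paired scores on the same samples are equal. AUCs are computed via the
#' Mann-Whitney identity; the variance of their difference uses the
#' structural-components (placement-value) covariance estimator: with
#' placement values \eqn{V^{10}_i} over positives and \eqn{V^{01}_j} over
#' negatives for each model,
#' \deqn{\widehat{Var}(\hat A_1 - \hat A_2) =
#'   \frac{s^{10}_{11} + s^{10}_{22} - 2 s^{10}_{12}}{n_1} +
#'   \frac{s^{01}_{11} + s^{01}_{22} - 2 s^{01}_{12}}{n_0},}
#' and \eqn{z = (\hat A_1 - \hat A_2) / \sqrt{\widehat{Var}}} is compared
#' to a standard normal (two-sided).
#'
#' Degenerate inputs follow fixed conventions: zero variance with zero AUC
#' difference gives p = 1; zero variance with a nonzero difference is an
#' error.
#'
#' @param scores_1,scores_2 paired numeric score vectors from the two
#'   models, on the same samples.
#' @param labels binary labels (see \code{\link{auroc}}).
#' @param positive positive class.
#' @return An object of class \code{"delong_result"}: list with
#'   \code{auc_1}, \code{auc_2}, \code{diff}, \code{var_diff}, \code{z},
#'   \code{p}.
#' @references DeLong, E.R., DeLong, D.M., Clarke-Pearson, D.L. (1988).
#'   Comparing the areas under two or more correlated receiver operating
#'   characteristic curves: a nonparametric approach. Biometrics 44.
#' @export
delong_test <- function(scores_1, scores_2, labels, positive = NULL) {
  stopifnot(length(scores_1) == length(labels),
            length(scores_2) == length(labels))
  pos <- binarize_labels(labels, positive)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present", call. = FALSE)
  }
  placement <- function(sc) {
    x <- sc[pos]; y <- sc[!pos]
    cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(cmp), v01 = colMeans(cmp))
  }
  p1 <- placement(scores_1)
  p2 <- placement(scores_2)
  auc1 <- mean(p1$v10)
  auc2 <- mean(p2$v10)
  cov_or_zero <- function(a, b) if (length(a) > 1L) stats::cov(a, b) else 0
  s10 <- matrix(c(cov_or_zero(p1$v10, p1$v10), cov_or_zero(p1$v10, p2$v10),
                  cov_or_zero(p2$v10, p1$v10), cov_or_zero(p2$v10, p2$v10)),
                2L)
  s01 <- matrix(c(cov_or_zero(p1$v01, p1$v01), cov_or_zero(p1$v01, p2$v01),
                  cov_or_zero(p2$v01, p1$v01), cov_or_zero(p2$v01, p2$v01)),
                2L)
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  d <- auc1 - auc2
  if (var_diff <= .Machine$double.eps) {
    if (abs(d) <= .Machine$double.eps) {
      z <- 0; p <- 1
    } else {
      stop("degenerate case: zero variance with nonzero AUC difference",
           call. = FALSE)
    }
  } else {
    z <- d / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_1 = auc1, auc_2 = auc2, diff = d,
                 var_diff = var_diff, z = z, p = p),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf(
    "DeLong test: AUC1 = %.4f, AUC2 = %.4f, diff = %+.4f (z = %.3f, p = %.4g)\n",
    x$auc_1, x$auc_2, x$diff, x$z, x$p))
  invisible(x)
}
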
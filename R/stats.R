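#' Per-protein Welch tests between two phenotype groups
#'
#' Runs a two-sided t test per protein between a disease group and a
#' reference group (typically healthy controls), with Bonferroni
#' correction \eqn{p_{corrected} = \min(1, p \times n)} where \eqn{n} is
#' the number of proteins tested on the panel, and standardized
#' mean-difference effect sizes. The unequal-variance Welch test is the
#' default; \code{var_equal = TRUE} gives the pooled-variance test.
#'
#' Significance stars follow the panel-wide convention: \code{"*"} for
#' \eqn{p < 0.01/n} and \code{"**"} for \eqn{p < 0.0001/n}. Proteins that
#' are constant in both groups with equal means are reported as t = 0,
#' p = 1.
#'
#' @param cohort an \code{\link{npx_cohort}}.
#' @param disease_label,reference_label phenotype labels of the two groups
#'   (each needs >= 2 samples).
#' @param n_correction number of tests for the Bonferroni factor; defaults
#'   to the number of proteins in the cohort.
#' @param var_equal use the pooled-variance t test instead of Welch.
#' @return data.frame with columns \code{protein}, \code{t}, \code{p},
#'   \code{p_corrected}, \code{cohen_d} (pooled-SD standardized mean
#'   difference), \code{welch_d} (mean difference over
#'   \eqn{\sqrt{(s_1^2 + s_2^2)/2}}), \code{significance}.
#' @export
welch_protein_tests <- function(cohort, disease_label, reference_label,
                                n_correction = NULL, var_equal = FALSE) {
  stopifnot(inherits(cohort, "npx_cohort"))
  g1 <- cohort$npx[cohort$labels == disease_label, , drop = FALSE]
  g0 <- cohort$npx[cohort$labels == reference_label, , drop = FALSE]
  if (nrow(g1) < 2L || nrow(g0) < 2L) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  n_correction <- n_correction %||% ncol(cohort$npx)
  res <- lapply(seq_len(ncol(g1)), function(j) {
    x <- g1[, j]; y <- g0[, j]
    tt <- tryCatch(stats::t.test(x, y, var.equal = var_equal),
                   error = function(e) NULL)
    if (is.null(tt)) {
      # both groups constant: equal means -> null convention, else infinite t
      if (isTRUE(all.equal(mean(x), mean(y)))) {
        tt <- list(statistic = 0, p.value = 1)
      } else {
        tt <- list(statistic = sign(mean(x) - mean(y)) * Inf, p.value = 0)
      }
    }
    s1 <- stats::var(x); s0 <- stats::var(y)
    sp <- sqrt(((length(x) - 1) * s1 + (length(y) - 1) * s0) /
               (length(x) + length(y) - 2))
    sw <- sqrt((s1 + s0) / 2)
    md <- mean(x) - mean(y)
    c(t = unname(tt$statistic), p = tt$p.value,
      cohen_d = if (sp > 0) md / sp else 0,
      welch_d = if (sw > 0) md / sw else 0)
  })
  res <- as.data.frame(do.call(rbind, res))
  out <- data.frame(protein = colnames(cohort$npx),
                    t = res$t, p = res$p,
                    p_corrected = pmin(1, res$p * n_correction),
                    cohen_d = res$cohen_d, welch_d = res$welch_d)
  out$significance <- ifelse(out$p < 1e-4 / n_correction, "**",
                      ifelse(out$p < 1e-2 / n_correction, "*", ""))
  out
}

#' Mann-Whitney U test (exact enumeration for small samples)
#'
#' Two-sided rank-sum test. For \eqn{\min(n_1, n_2) \le 8} the null
#' distribution of U is enumerated exactly over all group assignments of
#' the pooled values (ties handled by half-counting, so tied data are
#' supported); otherwise the normal approximation with midrank tie
#' correction and continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param exact force (\code{TRUE}) or forbid (\code{FALSE}) exact
#'   enumeration; default chooses by the small-sample rule.
#' @return List with \code{u} (U statistic of \code{x}), \code{p}
#'   (two-sided), \code{method}.
#' @export
mann_whitney_test <- function(x, y, exact = NULL) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be non-empty", call. = FALSE)
  u_stat <- function(a, b) {
    sum(outer(a, b, function(p, q) (p > q) + 0.5 * (p == q)))
  }
  u <- u_stat(x, y)
  mu <- n1 * n2 / 2
  if (is.null(exact)) exact <- min(n1, n2) <= 8L
  if (exact) {
    pooled <- c(x, y)
    combos <- utils::combn(n1 + n2, n1)
    us <- apply(combos, 2L, function(idx) {
      u_stat(pooled[idx], pooled[-idx])
    })
    p <- mean(abs(us - mu) >= abs(u - mu) - 1e-9)
    return(list(u = u, p = p, method = "exact enumeration"))
  }
  r <- rank(pooled <- c(x, y))
  ties <- table(pooled)
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(u = u, p = 1, method = "normal approximation"))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(u = u, p = min(1, 2 * stats::pnorm(-abs(z))),
       method = "normal approximation")
}

#' Compare per-class performance between two strata
#'
#' The stratification audit: given per-class evaluation reports from two
#' test strata (e.g. male-only vs female-only after excluding sex-specific
#' phenotypes), compares the per-class precision, recall and F1 vectors by
#' two-sided Mann-Whitney tests. The significance decision (the audits use
#' \eqn{\alpha = 0.01}) is left to the caller.
#'
#' @param report_a,report_b \code{eval_report}s over the same class set.
#' @return data.frame with columns \code{metric} and \code{p}.
#' @export
strata_performance_compare <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "eval_report"),
            inherits(report_b, "eval_report"))
  if (!setequal(report_a$per_class$class, report_b$per_class$class)) {
    stop("reports must cover the same class set", call. = FALSE)
  }
  if (nrow(report_a$per_class) < 2L) {
    stop("need at least 2 classes per group", call. = FALSE)
  }
  b <- report_b$per_class[match(report_a$per_class$class,
                                report_b$per_class$class), ]
  data.frame(
    metric = c("precision", "recall", "f1"),
    p = vapply(c("precision", "recall", "f1"), function(m) {
      mann_whitney_test(report_a$per_class[[m]], b[[m]])$p
    }, numeric(1)), row.names = NULL)
}
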
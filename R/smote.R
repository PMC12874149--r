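#' Classify minority samples into safe / danger / noise regions
#'
#' First step of borderline-SMOTE: for each sample of the minority class,
#' find its k nearest neighbors by Euclidean distance among \emph{all} other
#' samples and count the majority-class neighbors \eqn{m_i}. The sample is
#' tagged \code{danger} when \eqn{k/2 \le m_i < k} (on or near the class
#' border; these seed the synthesis), \code{noise} when \eqn{m_i = k}, and
#' \code{safe} when \eqn{m_i < k/2}. The \eqn{k/2} bound is real-valued, so
#' with \eqn{k = 5} the danger counts are \eqn{m_i \in \{3, 4\}}. Distance
#' ties are broken by ascending sample index.
#'
#' @param X numeric feature matrix (samples x features).
#' @param y class labels (length \code{nrow(X)}).
#' @param minority_label label whose samples are tagged.
#' @param k neighbor count (>= 1, < number of samples).
#' @return An object of class \code{"minority_regions"}: data.frame with
#'   columns \code{index} (row in \code{X}), \code{m} (majority-neighbor
#'   count) and \code{region}; attribute \code{k}.
#' @references Han, H., Wang, W.-Y., Mao, B.-H. (2005). Borderline-SMOTE: a
#'   new over-sampling method in imbalanced data sets learning.
#' @export
assign_minority_regions <- function(X, y, minority_label, k) {
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  if (k < 1L) fail_arg("k", "must be >= 1")
  if (k >= nrow(X) - 1L) {
    fail_arg("k", sprintf("must be < n_samples - 1 = %d", nrow(X) - 1L))
  }
  idx_min <- which(y == minority_label)
  if (!length(idx_min)) {
    fail_arg("minority_label", "no samples carry this label")
  }
  d <- as.matrix(stats::dist(X))
  m <- integer(length(idx_min))
  for (j in seq_along(idx_min)) {
    i <- idx_min[j]
    others <- setdiff(seq_len(nrow(X)), i)
    nn <- others[order(d[i, others], others)][seq_len(k)]
    m[j] <- sum(y[nn] != minority_label)
  }
  region <- ifelse(m == k, "noise", ifelse(m >= k / 2, "danger", "safe"))
  structure(data.frame(index = idx_min, m = m, region = region),
            k = k, class = c("minority_regions", "data.frame"))
}

#' Interpolate a synthetic sample
#'
#' The borderline-SMOTE interpolation rule
#' \eqn{x_{new} = x_i + \lambda (x_z - x_i)} with \eqn{\lambda \in [0, 1]}:
#' the synthetic point lies on the closed segment between a danger-region
#' seed \eqn{x_i} and a partner \eqn{x_z}.
#'
#' @param x_i,x_z numeric vectors of equal length.
#' @param lambda interpolation weight in \[0, 1\].
#' @return Numeric vector \code{x_i + lambda * (x_z - x_i)}.
#' @export
synthesize_sample <- function(x_i, x_z, lambda) {
  if (length(x_i) != length(x_z)) {
    fail_arg("x_z", "must have the same length as x_i")
  }
  if (!is.numeric(lambda) || length(lambda) != 1L ||
      lambda < 0 || lambda > 1) {
    fail_arg("lambda", "must be a single value in [0, 1]")
  }
  x_i + lambda * (x_z - x_i)
}

#' Borderline-SMOTE oversampling
#'
#' Oversamples every non-majority class up to the majority-class count.
#' Classes are processed one-vs-rest in ascending label order, with all
#' other classes pooled as the majority. Only danger-region samples (see
#' \code{\link{assign_minority_regions}}) seed the synthesis; for each
#' synthetic row a partner \eqn{x_z} is drawn uniformly from the seed's k
#' nearest neighbors within the minority class (or within all samples when
#' \code{neighbor_pool = "all"}) and interpolated with
#' \code{\link{synthesize_sample}} at \eqn{\lambda \sim U[0, 1]}. Original
#' rows are preserved unchanged; a class with no danger points (or no
#' same-class partner) is returned unaugmented with a warning.
#'
#' @inheritParams assign_minority_regions
#' @param k neighbor count used both for region tagging and partner
#'   selection (default 5).
#' @param seed integer seed; identical seeds give identical output.
#' @param neighbor_pool partner pool: \code{"minority"} (same-class
#'   neighbors) or \code{"all"}.
#' @return List with \code{X} (original rows then synthetic rows), \code{y},
#'   and \code{provenance}: a data.frame logging, per synthetic row, the
#'   class, seed row index, partner row index (both into the original
#'   \code{X}) and \eqn{\lambda} — every synthetic row is auditable as an
#'   affine point on its logged segment.
#' @examples
#' set.seed(1)
#' X <- rbind(matrix(rnorm(100), 50), matrix(rnorm(20, 1.5), 10))
#' y <- rep(c("maj", "min"), c(50, 10))
#' aug <- borderline_smote(X, y, k = 5, seed = 7)
#' table(aug$y)
#' @export
borderline_smote <- function(X, y, k = 5L, seed = 1L,
                             neighbor_pool = c("minority", "all")) {
  neighbor_pool <- match.arg(neighbor_pool)
  X <- as.matrix(X)
  y <- as.character(y)
  stopifnot(nrow(X) == length(y))
  counts <- table(y)
  if (length(counts) < 2L) {
    fail_arg("y", "need at least 2 classes")
  }
  target <- max(counts)
  syn_rows <- list()
  syn_y <- character()
  prov <- list()
  d <- as.matrix(stats::dist(X))
  with_seed(seed, {
    for (cls in sort_labels(names(counts))) {
      deficit <- target - counts[[cls]]
      if (deficit == 0L) next
      k_eff <- min(k, nrow(X) - 2L)
      regions <- assign_minority_regions(X, y, cls, k_eff)
      danger <- regions$index[regions$region == "danger"]
      if (!length(danger)) {
        warning(sprintf(
          "class '%s': no danger-region samples; returned unaugmented", cls),
          call. = FALSE)
        next
      }
      pool_idx <- if (neighbor_pool == "minority") which(y == cls)
                  else seq_len(nrow(X))
      # k nearest partners per danger seed, ties by ascending index
      partners <- lapply(danger, function(i) {
        cand <- setdiff(pool_idx, i)
        cand[order(d[i, cand], cand)][seq_len(min(k, length(cand)))]
      })
      ok <- lengths(partners) > 0L
      if (!any(ok)) {
        warning(sprintf(
          "class '%s': no neighbor partners available; returned unaugmented",
          cls), call. = FALSE)
        next
      }
      danger <- danger[ok]
      partners <- partners[ok]
      for (s in seq_len(deficit)) {
        si <- sample.int(length(danger), 1L)
        i <- danger[si]
        z <- partners[[si]][sample.int(length(partners[[si]]), 1L)]
        lambda <- stats::runif(1L)
        syn_rows[[length(syn_rows) + 1L]] <-
          synthesize_sample(X[i, ], X[z, ], lambda)
        syn_y <- c(syn_y, cls)
        prov[[length(prov) + 1L]] <-
          data.frame(class = cls, seed_index = i, partner_index = z,
                     lambda = lambda)
      }
    }
  })
  provenance <- if (length(prov)) do.call(rbind, prov) else {
    data.frame(class = character(), seed_index = integer(),
               partner_index = integer(), lambda = numeric())
  }
  X_aug <- if (length(syn_rows)) rbind(X, do.call(rbind, syn_rows)) else X
  rownames(X_aug) <- NULL
  list(X = X_aug, y = c(y, syn_y), provenance = provenance)
}

#' Write a synthetic-row provenance log
#'
#' @param provenance the \code{provenance} element of a
#'   \code{\link{borderline_smote}} result.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_provenance <- function(provenance, path) {
  utils::write.table(provenance, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
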
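#' NPX cohort container
#'
#' Holds a samples x proteins matrix of NPX values (Olink's relative
#' log2-scale protein abundance) together with per-sample phenotype labels
#' and optional demographic metadata (sex, age, BMI). This is the input type
#' of every modelling function in the package.
#'
#' @param npx numeric matrix, samples in rows, proteins in columns. Row and
#'   column names are used as sample and protein ids; defaults are generated
#'   when absent.
#' @param labels character vector of per-sample phenotype labels.
#' @param meta optional data.frame of per-sample covariates (columns among
#'   \code{sex}, \code{age}, \code{bmi}).
#' @param truth optional \code{sim_config} that generated the cohort
#'   (attached by \code{\link{simulate_cohort}}).
#' @return An object of class \code{"npx_cohort"}.
#' @export
npx_cohort <- function(npx, labels, meta = NULL, truth = NULL) {
  npx <- as.matrix(npx)
  storage.mode(npx) <- "double"
  labels <- as.character(labels)
  if (nrow(npx) != length(labels)) {
    fail_arg("labels", sprintf("length %d but matrix has %d rows",
                               length(labels), nrow(npx)))
  }
  if (any(!nzchar(labels)) || anyNA(labels)) {
    fail_arg("labels", "labels must be non-empty strings")
  }
  if (is.null(colnames(npx))) {
    colnames(npx) <- sprintf("P%04d", seq_len(ncol(npx)))
  }
  if (is.null(rownames(npx))) {
    rownames(npx) <- sprintf("S%05d", seq_len(nrow(npx)))
  }
  if (anyDuplicated(colnames(npx))) {
    fail_arg("npx", sprintf(
      "duplicate protein columns: %s",
      paste(unique(colnames(npx)[duplicated(colnames(npx))]), collapse = ", ")))
  }
  if (!is.null(meta)) {
    meta <- as.data.frame(meta)
    if (nrow(meta) != nrow(npx)) {
      fail_arg("meta", "row count must match the NPX matrix")
    }
  }
  structure(list(npx = npx, labels = labels, meta = meta, truth = truth),
            class = "npx_cohort")
}

#' @export
print.npx_cohort <- function(x, ...) {
  tab <- sort(table(x$labels), decreasing = TRUE)
  cat(sprintf("NPX cohort: %d samples x %d proteins, %d phenotype class(es)\n",
              nrow(x$npx), ncol(x$npx), length(tab)))
  shown <- utils::head(tab, 8L)
  cat("  classes:", paste(sprintf("%s(%d)", names(shown), shown),
                          collapse = " "),
      if (length(tab) > 8L) "..." else "", "\n")
  if (!is.null(x$meta)) {
    cat("  metadata:", paste(names(x$meta), collapse = ", "), "\n")
  }
  if (!is.null(x$truth)) cat("  simulated (truth config attached)\n")
  invisible(x)
}

#' @export
dim.npx_cohort <- function(x) dim(x$npx)

# Subset a cohort by sample index and/or protein columns (internal).
cohort_subset <- function(cohort, rows = NULL, cols = NULL) {
  npx <- cohort$npx
  labels <- cohort$labels
  meta <- cohort$meta
  if (!is.null(rows)) {
    npx <- npx[rows, , drop = FALSE]
    labels <- labels[rows]
    if (!is.null(meta)) meta <- meta[rows, , drop = FALSE]
  }
  if (!is.null(cols)) npx <- npx[, cols, drop = FALSE]
  npx_cohort(npx, labels, meta = meta, truth = cohort$truth)
}
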
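#' Read an NPX cohort table
#'
#' Reads a delimited text feature table with samples as rows: columns
#' \code{sample_id}, \code{phenotype}, optional metadata columns
#' (\code{sex}, \code{age}, \code{bmi}), then one numeric column per
#' protein. The delimiter is auto-detected between tab and comma unless
#' given explicitly.
#'
#' Empty cells in protein columns are recorded as missing and reported via
#' a message; by default missing values are kept as \code{NA} (model fitting
#' rejects them), or imputed by the per-protein median with
#' \code{impute = TRUE} for prediction-only use. A non-numeric protein cell
#' is a parse error reported with its row and column.
#'
#' @param path file path.
#' @param dialect \code{"auto"}, \code{"tab"} or \code{"comma"}.
#' @param impute impute missing NPX cells with the per-protein median.
#' @return An \code{\link{npx_cohort}}.
#' @seealso \code{\link{write_npx_table}}
#' @export
read_npx_table <- function(path, dialect = c("auto", "tab", "comma"),
                           impute = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- switch(dialect, tab = "\t", comma = ",",
                auto = if (grepl("\t", header)) "\t" else ",")
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = c("", "NA"))
  if (!all(c("sample_id", "phenotype") %in% names(df))) {
    stop("header must contain `sample_id` and `phenotype` columns",
         call. = FALSE)
  }
  meta_cols <- intersect(c("sex", "age", "bmi"), names(df))
  prot_cols <- names(df)[!names(df) %in% c("sample_id", "phenotype",
                                           meta_cols)]
  if (!length(prot_cols)) stop("no protein columns found", call. = FALSE)
  dup <- unique(prot_cols[duplicated(prot_cols)])
  if (length(dup)) {
    stop(sprintf("duplicate protein column(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  raw <- as.matrix(df[, prot_cols, drop = FALSE])
  npx <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw),
                                 dimnames = list(df$sample_id, prot_cols)))
  bad <- which(is.na(npx) & !is.na(raw), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric NPX value '%s' at row %d, column '%s'",
                 raw[bad[1L, 1L], bad[1L, 2L]], bad[1L, 1L],
                 prot_cols[bad[1L, 2L]]), call. = FALSE)
  }
  n_missing <- sum(is.na(npx))
  if (n_missing > 0L) {
    message(sprintf("%d missing NPX cell(s) in %s", n_missing, basename(path)))
    if (impute) {
      for (j in which(colSums(is.na(npx)) > 0L)) {
        npx[is.na(npx[, j]), j] <- stats::median(npx[, j], na.rm = TRUE)
      }
    }
  }
  meta <- if (length(meta_cols)) {
    m <- df[, meta_cols, drop = FALSE]
    m[] <- lapply(m, function(x) suppressWarnings(as.numeric(x)))
    m
  } else NULL
  npx_cohort(npx, df$phenotype, meta = meta)
}

#' Write an NPX cohort table
#'
#' Writes the tab-delimited layout read back by
#' \code{\link{read_npx_table}}; simulated and real cohorts are
#' interchangeable on disk.
#'
#' @param cohort an \code{\link{npx_cohort}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_npx_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "npx_cohort"))
  df <- data.frame(sample_id = rownames(cohort$npx),
                   phenotype = cohort$labels,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(cohort$meta)) df <- cbind(df, cohort$meta)
  df <- cbind(df, as.data.frame(cohort$npx, check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy configuration file
#'
#' Reads a YAML mapping of category name to phenotype label list; the
#' reserved key \code{terminal} lists labels that form their own
#' first-stage class. Disjointness and non-emptiness are validated.
#'
#' @param path YAML file path.
#' @return An \code{\link{taxonomy}} object.
#' @examples
#' f <- tempfile(fileext = ".yml")
#' writeLines(c("blood: [AML, CLL]", "psych: [BD, SZ]",
#'              "terminal: [HEALTHY]"), f)
#' read_taxonomy(f)
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  spec <- yaml::read_yaml(path)
  if (!is.list(spec) || is.null(names(spec))) {
    stop("taxonomy file must map category names to label lists", call. = FALSE)
  }
  terminal <- as.character(spec[["terminal"]] %||% character())
  cats <- spec[setdiff(names(spec), "terminal")]
  taxonomy(lapply(cats, as.character), terminal = terminal)
}

#' @rdname read_taxonomy
#' @param tax an \code{npx_taxonomy} to write.
#' @export
write_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "npx_taxonomy"))
  out <- tax$categories
  if (length(tax$terminal)) out$terminal <- tax$terminal
  yaml::write_yaml(lapply(out, as.list), path)
  invisible(path)
}

#' Check that a taxonomy covers a cohort's labels
#'
#' Report-only audit: lists the cohort phenotype labels that are absent from
#' the taxonomy. An empty result means full coverage.
#'
#' @param cohort an \code{\link{npx_cohort}}.
#' @param tax an \code{\link{taxonomy}}.
#' @return Character vector of unmapped labels (possibly empty).
#' @export
validate_cohort_against_taxonomy <- function(cohort, tax) {
  stopifnot(inherits(cohort, "npx_cohort"), inherits(tax, "npx_taxonomy"))
  setdiff(unique(cohort$labels), label_order(tax))
}
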
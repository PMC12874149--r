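#' Disease taxonomy for hierarchical classification
#'
#' A taxonomy partitions the phenotype labels of a cohort into disjoint
#' categories (equivalence classes) that define the first classification
#' stage, plus an optional set of terminal labels that are their own
#' first-stage class (typically the healthy controls). First-stage classes
#' are the category names followed by the terminal labels, in the order
#' given; that order also fixes the label order of every probability vector
#' and report produced downstream.
#'
#' @param categories named list; each element is a character vector of
#'   phenotype labels belonging to that category.
#' @param terminal character vector of labels that bypass the second stage
#'   (default none).
#' @return An object of class \code{"npx_taxonomy"} with elements
#'   \code{categories} and \code{terminal}.
#' @examples
#' tax <- taxonomy(list(blood = c("AML", "CLL"), psych = c("BD", "SZ")),
#'                 terminal = "HEALTHY")
#' first_stage_classes(tax)
#' label_order(tax)
#' @export
taxonomy <- function(categories, terminal = character()) {
  if (!is.list(categories) || is.null(names(categories)) ||
      any(!nzchar(names(categories)))) {
    fail_arg("categories", "must be a named list of label vectors")
  }
  categories <- lapply(categories, as.character)
  terminal <- as.character(terminal)
  if (any(lengths(categories) == 0L)) {
    fail_arg("categories", sprintf(
      "empty category: %s",
      paste(names(categories)[lengths(categories) == 0L], collapse = ", ")))
  }
  all_labels <- c(unlist(categories, use.names = FALSE), terminal)
  dup <- unique(all_labels[duplicated(all_labels)])
  if (length(dup)) {
    fail_arg("categories", sprintf(
      "labels assigned to more than one category/terminal: %s",
      paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(names(categories))) {
    fail_arg("categories", "duplicated category names")
  }
  clash <- intersect(names(categories), all_labels)
  if (length(clash)) {
    fail_arg("categories", sprintf(
      "category name also used as a label: %s", paste(clash, collapse = ", ")))
  }
  structure(list(categories = categories, terminal = terminal),
            class = "npx_taxonomy")
}

#' @export
print.npx_taxonomy <- function(x, ...) {
  cat(sprintf("Disease taxonomy: %d categories, %d terminal label(s), %d labels\n",
              length(x$categories), length(x$terminal),
              length(label_order(x))))
  for (nm in names(x$categories)) {
    cat(sprintf("  %s: %s\n", nm, paste(x$categories[[nm]], collapse = ", ")))
  }
  if (length(x$terminal)) {
    cat(sprintf("  (terminal): %s\n", paste(x$terminal, collapse = ", ")))
  }
  invisible(x)
}

#' @rdname taxonomy
#' @param tax an \code{npx_taxonomy}.
#' @export
first_stage_classes <- function(tax) {
  stopifnot(inherits(tax, "npx_taxonomy"))
  c(names(tax$categories), tax$terminal)
}

#' @rdname taxonomy
#' @export
label_order <- function(tax) {
  stopifnot(inherits(tax, "npx_taxonomy"))
  c(unlist(tax$categories, use.names = FALSE), tax$terminal)
}

#' Map phenotype labels to their first-stage class
#'
#' @param tax an \code{npx_taxonomy}.
#' @param labels character vector of phenotype labels.
#' @return Character vector of first-stage class names (the category name for
#'   categorized labels, the label itself for terminal labels).
#' @export
category_of <- function(tax, labels) {
  stopifnot(inherits(tax, "npx_taxonomy"))
  labels <- as.character(labels)
  map <- rep(names(tax$categories), lengths(tax$categories))
  names(map) <- unlist(tax$categories, use.names = FALSE)
  map <- c(map, stats::setNames(tax$terminal, tax$terminal))
  unknown <- setdiff(unique(labels), names(map))
  if (length(unknown)) {
    stop(sprintf("labels not covered by the taxonomy: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  unname(map[labels])
}
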
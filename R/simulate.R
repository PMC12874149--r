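#' Configure a synthetic NPX cohort
#'
#' Defines the generative model for a labeled synthetic cohort that mimics
#' the structure of a multi-disease plasma proteomics study: a hierarchical
#' mean model on a relative log2 (NPX) scale, class imbalance expressed
#' directly as per-class sample counts, independent Gaussian measurement
#' noise, and optional demographic covariates coupled to a subset of
#' proteins. Baseline NPX is 0 for every protein: NPX is a relative scale,
#' so only shifts matter.
#'
#' The mean of protein \eqn{p} for a sample with label \eqn{l} in category
#' \eqn{c} is \eqn{\mu_{lp} = \delta^{cat}_{cp} + \delta^{dis}_{lp} +
#' h_p(z)}, where the two \eqn{\delta} terms are the planted category- and
#' disease-level marker shifts (in NPX log2 units) and \eqn{h_p(z)} is the
#' optional covariate term: linear in the standardized covariate, or a step
#' function of it when a threshold is given (NPX-covariate relationships in
#' real cohorts are typically nonlinear).
#'
#' @param n_per_class named integer vector: samples per phenotype label.
#' @param taxonomy an \code{\link{taxonomy}} covering every label in
#'   \code{n_per_class}.
#' @param n_proteins number of protein features.
#' @param category_markers named list keyed by category name; each element a
#'   data.frame with columns \code{protein} (column index) and \code{shift}
#'   (NPX log2 units) applied to every label of that category.
#' @param disease_markers named list keyed by phenotype label, same layout,
#'   applied to that label only.
#' @param noise_sd Gaussian noise standard deviation in NPX units (> 0).
#' @param covariate_spec optional data.frame with columns \code{protein},
#'   \code{covariate} (one of \code{"age"}, \code{"sex"}, \code{"bmi"}),
#'   \code{slope}, and optional \code{threshold}; rows with a finite
#'   threshold contribute \code{slope * 1(covariate > threshold)}, others
#'   \code{slope * standardized covariate}.
#' @param with_meta logical; generate sex/age/BMI metadata (forced on when
#'   \code{covariate_spec} is given).
#' @param seed integer seed; identical configs give bit-identical cohorts.
#' @return An object of class \code{"sim_config"}.
#' @seealso \code{\link{simulate_cohort}}, \code{\link{summarize_planted_effects}}
#' @export
sim_config <- function(n_per_class, taxonomy, n_proteins,
                       category_markers = list(), disease_markers = list(),
                       noise_sd = 1, covariate_spec = NULL,
                       with_meta = FALSE, seed = 1L) {
  if (is.null(names(n_per_class)) || any(!nzchar(names(n_per_class)))) {
    fail_arg("n_per_class", "must be a named vector of per-label counts")
  }
  n_per_class <- round(n_per_class)
  if (any(n_per_class < 0)) fail_arg("n_per_class", "counts must be >= 0")
  if (!inherits(taxonomy, "npx_taxonomy")) {
    fail_arg("taxonomy", "must be an npx_taxonomy object")
  }
  missing_labels <- setdiff(names(n_per_class), label_order(taxonomy))
  if (length(missing_labels)) {
    fail_arg("taxonomy_spec", sprintf(
      "labels not mapped to any category: %s",
      paste(missing_labels, collapse = ", ")))
  }
  n_proteins <- as.integer(n_proteins)
  if (n_proteins < 1L) fail_arg("n_proteins", "must be >= 1")
  check_markers <- function(mk, field, keys) {
    if (length(mk) == 0L) return(invisible())
    if (is.null(names(mk))) fail_arg(field, "must be a named list")
    bad <- setdiff(names(mk), keys)
    if (length(bad)) {
      fail_arg(field, sprintf("unknown key(s): %s", paste(bad, collapse = ", ")))
    }
    for (nm in names(mk)) {
      m <- mk[[nm]]
      if (!all(c("protein", "shift") %in% names(m))) {
        fail_arg(field, sprintf("entry '%s' needs columns protein, shift", nm))
      }
      if (any(m$protein < 1L | m$protein > n_proteins)) {
        fail_arg(field, sprintf("entry '%s' has protein index out of 1..%d",
                                nm, n_proteins))
      }
    }
  }
  check_markers(category_markers, "category_markers", names(taxonomy$categories))
  check_markers(disease_markers, "disease_markers", names(n_per_class))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0) {
    fail_arg("noise_sd", "must be a single value > 0")
  }
  if (!is.null(covariate_spec)) {
    covariate_spec <- as.data.frame(covariate_spec)
    need <- c("protein", "covariate", "slope")
    if (!all(need %in% names(covariate_spec))) {
      fail_arg("covariate_spec", "needs columns protein, covariate, slope")
    }
    if (!all(covariate_spec$covariate %in% c("age", "sex", "bmi"))) {
      fail_arg("covariate_spec", "covariate must be one of age, sex, bmi")
    }
    if (any(covariate_spec$protein < 1L | covariate_spec$protein > n_proteins)) {
      fail_arg("covariate_spec", sprintf("protein index out of 1..%d", n_proteins))
    }
    if (is.null(covariate_spec$threshold)) covariate_spec$threshold <- NA_real_
    with_meta <- TRUE
  }
  structure(list(n_per_class = n_per_class, taxonomy = taxonomy,
                 n_proteins = n_proteins,
                 category_markers = category_markers,
                 disease_markers = disease_markers,
                 noise_sd = noise_sd, covariate_spec = covariate_spec,
                 with_meta = isTRUE(with_meta), seed = as.integer(seed)),
            class = "sim_config")
}

# Generative moments of the demographic covariates; used both to draw them
# and to standardize the linear covariate term.
.cov_moments <- list(age = c(mean = 55, sd = 12),
                     bmi = c(mean = 26, sd = 4),
                     sex = c(mean = 0.5, sd = 0.5))

#' Simulate a labeled NPX cohort
#'
#' Draws a cohort from a \code{\link{sim_config}}: per-class sample counts
#' are matched exactly, each NPX value is the sum of a zero baseline, the
#' planted category and disease marker shifts, the optional covariate term,
#' and independent Gaussian noise. The same config (including its seed)
#' always yields a bit-identical cohort.
#'
#' @param config a \code{\link{sim_config}}.
#' @return An \code{\link{npx_cohort}} carrying \code{config} as its
#'   \code{truth} element.
#' @examples
#' tax <- taxonomy(list(grp = c("A", "B")))
#' cfg <- sim_config(c(A = 7, B = 3), tax, n_proteins = 5, seed = 42)
#' cohort <- simulate_cohort(cfg)
#' table(cohort$labels)
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    fail_arg("config", "must be a sim_config object")
  }
  n_total <- sum(config$n_per_class)
  labels <- rep(names(config$n_per_class), config$n_per_class)
  with_seed(config$seed, {
    meta <- NULL
    if (config$with_meta) {
      meta <- data.frame(
        sex = stats::rbinom(n_total, 1L, 0.5),
        age = stats::rnorm(n_total, .cov_moments$age["mean"],
                           .cov_moments$age["sd"]),
        bmi = stats::rnorm(n_total, .cov_moments$bmi["mean"],
                           .cov_moments$bmi["sd"]))
    }
    mu <- matrix(0, n_total, config$n_proteins)
    cats <- category_of(config$taxonomy, labels)
    for (nm in names(config$category_markers)) {
      m <- config$category_markers[[nm]]
      rows <- which(cats == nm)
      for (i in seq_len(nrow(m))) {
        mu[rows, m$protein[i]] <- mu[rows, m$protein[i]] + m$shift[i]
      }
    }
    for (nm in names(config$disease_markers)) {
      m <- config$disease_markers[[nm]]
      rows <- which(labels == nm)
      for (i in seq_len(nrow(m))) {
        mu[rows, m$protein[i]] <- mu[rows, m$protein[i]] + m$shift[i]
      }
    }
    if (!is.null(config$covariate_spec)) {
      cs <- config$covariate_spec
      for (i in seq_len(nrow(cs))) {
        z <- meta[[cs$covariate[i]]]
        term <- if (is.finite(cs$threshold[i])) {
          cs$slope[i] * as.numeric(z > cs$threshold[i])
        } else {
          mom <- .cov_moments[[cs$covariate[i]]]
          cs$slope[i] * (z - mom["mean"]) / mom["sd"]
        }
        mu[, cs$protein[i]] <- mu[, cs$protein[i]] + term
      }
    }
    npx <- mu + matrix(stats::rnorm(n_total * config$n_proteins,
                                    sd = config$noise_sd),
                       n_total, config$n_proteins)
    colnames(npx) <- sprintf("P%04d", seq_len(config$n_proteins))
    rownames(npx) <- sprintf("S%05d", seq_len(n_total))
    npx_cohort(npx, labels, meta = meta, truth = config)
  })
}

#' Tabulate planted versus recovered marker effects
#'
#' For every planted marker in the truth config of a simulated cohort,
#' reports the theoretical mean shift alongside the empirical shift
#' recovered from the cohort (mean NPX of carrier samples minus mean NPX of
#' all other samples, on the marker's protein column). When markers overlap
#' on a protein the non-carrier contrast absorbs the other shifts; keep
#' planted markers on distinct proteins for clean recovery checks.
#'
#' @param cohort an \code{\link{npx_cohort}} produced by
#'   \code{\link{simulate_cohort}} (must carry its truth config).
#' @return data.frame with columns \code{level} ("category"/"disease"),
#'   \code{label}, \code{protein}, \code{theoretical_shift},
#'   \code{empirical_shift}.
#' @export
summarize_planted_effects <- function(cohort) {
  if (!inherits(cohort, "npx_cohort") || is.null(cohort$truth)) {
    stop("cohort does not carry its generating config (`truth`); ",
         "only simulated cohorts are supported", call. = FALSE)
  }
  cfg <- cohort$truth
  cats <- category_of(cfg$taxonomy, cohort$labels)
  one <- function(level, label, carrier, m) {
    data.frame(level = level, label = label, protein = m$protein,
               theoretical_shift = m$shift,
               empirical_shift = vapply(m$protein, function(p) {
                 mean(cohort$npx[carrier, p]) - mean(cohort$npx[!carrier, p])
               }, numeric(1)))
  }
  out <- list()
  for (nm in names(cfg$category_markers)) {
    out[[length(out) + 1L]] <-
      one("category", nm, cats == nm, cfg$category_markers[[nm]])
  }
  for (nm in names(cfg$disease_markers)) {
    out[[length(out) + 1L]] <-
      one("disease", nm, cohort$labels == nm, cfg$disease_markers[[nm]])
  }
  if (!length(out)) {
    return(data.frame(level = character(), label = character(),
                      protein = integer(), theoretical_shift = numeric(),
                      empirical_shift = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
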
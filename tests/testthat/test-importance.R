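# Small two-class cohort with one dominant marker; cheap enough that
# models refit in well under a second.
marker_cohort <- function(seed, n = 30, p = 6, shift = 4) {
  tax <- taxonomy(list(g = c("A", "B")))
  simulate_cohort(sim_config(
    c(A = n, B = n), tax, n_proteins = p,
    disease_markers = list(A = data.frame(protein = 1, shift = shift)),
    noise_sd = 1, seed = seed))
}

test_that("constant columns have exactly zero importance", {
  co <- marker_cohort(1)
  co$npx[, 3] <- 7  # constant column: permutation is a no-op
  fit <- fit_node(node_spec("ridge"), co$npx, co$labels, seed = 1)
  predictor <- function(X) {
    fit$levels[max.col(node_probs(fit, X), ties.method = "first")]
  }
  imp <- permutation_importance(predictor, co$npx, co$labels,
                                n_perm = 5, seed = 2)
  expect_identical(unname(imp[3]), 0)
  expect_gt(imp[1], 0)
})

test_that("exact enumeration matches an independent brute-force oracle", {
  co <- marker_cohort(2)
  fit <- fit_node(node_spec("ridge"), co$npx, co$labels, seed = 1)
  predictor <- function(X) {
    fit$levels[max.col(node_probs(fit, X), ties.method = "first")]
  }
  Xt <- co$npx[c(1, 2, 31), ]
  yt <- co$labels[c(1, 2, 31)]
  imp <- permutation_importance(predictor, Xt, yt, metric = "accuracy",
                                exact = TRUE)
  # oracle: enumerate all 3! orderings of each column by hand
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  base <- mean(predictor(Xt) == yt)
  for (j in seq_len(ncol(Xt))) {
    drops <- vapply(perms, function(ord) {
      Xp <- Xt
      Xp[, j] <- Xt[ord, j]
      base - mean(predictor(Xp) == yt)
    }, numeric(1))
    expect_equal(unname(imp[j]), mean(drops), tolerance = 1e-12)
  }
})

test_that("sampled importance is deterministic given the seed", {
  co <- marker_cohort(3)
  fit <- fit_node(node_spec("ridge"), co$npx, co$labels, seed = 1)
  predictor <- function(X) {
    fit$levels[max.col(node_probs(fit, X), ties.method = "first")]
  }
  i1 <- permutation_importance(predictor, co$npx, co$labels, n_perm = 10,
                               seed = 5)
  i2 <- permutation_importance(predictor, co$npx, co$labels, n_perm = 10,
                               seed = 5)
  expect_identical(i1, i2)
  expect_error(permutation_importance(predictor, co$npx[0, ], character()),
               "empty")
})

test_that("the dominant marker ranks first across seeds", {
  hits <- vapply(1:10, function(s) {
    co <- marker_cohort(100 + s)
    sp <- stratified_split(co, 0.6, seed = s)
    fit <- fit_node(node_spec("ridge"), sp$train$npx, sp$train$labels,
                    seed = s)
    predictor <- function(X) {
      fit$levels[max.col(node_probs(fit, X), ties.method = "first")]
    }
    imp <- permutation_importance(predictor, sp$test$npx, sp$test$labels,
                                  n_perm = 5, seed = s)
    which.max(imp) == 1L
  }, logical(1))
  expect_gte(sum(hits), 9L)
})

test_that("raising a planted shift never lowers its median importance", {
  med_imp <- vapply(c(1, 2.5, 4), function(shift) {
    imps <- vapply(1:5, function(s) {
      co <- marker_cohort(200 + s, shift = shift)
      sp <- stratified_split(co, 0.6, seed = s)
      fit <- fit_node(node_spec("ridge"), sp$train$npx, sp$train$labels,
                      seed = s)
      predictor <- function(X) {
        fit$levels[max.col(node_probs(fit, X), ties.method = "first")]
      }
      permutation_importance(predictor, sp$test$npx, sp$test$labels,
                             n_perm = 5, seed = s)[1]
    }, numeric(1))
    median(imps)
  }, numeric(1))
  expect_true(all(diff(med_imp) >= 0))
})

test_that("stacked importance aggregates one-vs-rest contributions", {
  co <- demo_cohort(seed = 41, n_proteins = 12,
                    n = c(AML = 12, CLL = 12, BD = 12, SZ = 12,
                          HEALTHY = 12))
  sp <- stratified_split(co, 0.6, seed = 1)
  m <- suppressWarnings(fit_fast(sp$train, demo_taxonomy(), seed = 2))
  tab <- stacked_importance(m, sp$test, n_perm = 3, seed = 3)
  expect_s3_class(tab, "importance_table")
  expect_equal(nrow(tab), 12L)
  expect_true(all(tab$occurrence >= 0 & tab$occurrence <= 5))
  expect_equal(tab$rank, 1:12)
  # occurrence is the count of strictly positive per-disease contributions
  disease_cols <- intersect(names(tab), m$label_order)
  expect_equal(tab$occurrence,
               as.integer(rowSums(tab[disease_cols] > 0)))
  expect_equal(tab$stacked_score,
               rowSums(as.matrix(tab[disease_cols]) *
                       (as.matrix(tab[disease_cols]) > 0)))
  # ranking: occurrence desc, then stacked score desc
  expect_true(all(diff(tab$occurrence) <= 0))

  # a model that ignores the features entirely: occurrence 0 everywhere
  m0 <- suppressMessages(two_stage(
    sp$train, demo_taxonomy(), first_stage = node_spec("dummy"),
    second_stage = list(blood = node_spec("dummy"),
                        psych = node_spec("dummy")),
    oversample = FALSE, seed = 1))
  tab0 <- stacked_importance(m0, sp$test, n_perm = 2, seed = 1)
  expect_true(all(tab0$occurrence == 0))
})

test_that("top_k returns a valid ordered feature subset", {
  co <- demo_cohort(seed = 42, n_proteins = 12,
                    n = c(AML = 12, CLL = 12, BD = 12, SZ = 12,
                          HEALTHY = 12))
  sp <- stratified_split(co, 0.6, seed = 1)
  m <- suppressWarnings(fit_fast(sp$train, demo_taxonomy(), seed = 2))
  tab <- stacked_importance(m, sp$test, n_perm = 3, seed = 3)
  expect_equal(top_k(tab, 12), tab$protein)
  expect_equal(top_k(tab, 3), tab$protein[1:3])
  expect_error(top_k(tab, 0), "k")
  expect_error(top_k(tab, 13), "k")
  # the selection feeds a feature-restricted refit without error
  m_top <- suppressWarnings(restrict_to_features(
    sp$train, demo_taxonomy(), features = top_k(tab, 6),
    first_stage = fast_specs()$first_stage,
    second_stage = fast_specs()$second_stage, seed = 2))
  expect_s3_class(m_top, "two_stage")
})
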
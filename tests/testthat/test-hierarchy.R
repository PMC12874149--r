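test_that("stratified split uses ceiling allocation per class", {
  tax <- taxonomy(list(g = c("A", "B")))
  co <- simulate_cohort(sim_config(c(A = 137, B = 10), tax, n_proteins = 2,
                                   seed = 1))
  sp <- stratified_split(co, 0.7, seed = 3)
  expect_equal(sum(sp$train$labels == "A"), 96L)  # ceil(0.7 * 137)
  expect_equal(sum(sp$train$labels == "B"), 7L)
  expect_equal(sum(sp$test$labels == "B"), 3L)
  # disjoint and exhaustive
  expect_equal(nrow(sp$train$npx) + nrow(sp$test$npx), 147L)
  expect_length(intersect(rownames(sp$train$npx), rownames(sp$test$npx)), 0L)

  sp2 <- stratified_split(co, 0.7, seed = 3)
  expect_identical(rownames(sp$train$npx), rownames(sp2$train$npx))

  co1 <- npx_cohort(co$npx, replace(co$labels, co$labels == "B",
                                    c("B", rep("C", 9))))
  expect_error(stratified_split(co1, 0.7), "B.*merge")
  expect_error(stratified_split(co, 1.2), "train_fraction")
})

test_that("hierarchy structure follows the taxonomy, with pass-through nodes", {
  tax <- taxonomy(list(C1 = c("A", "B"), C2 = "C"), terminal = "H")
  set.seed(1)
  X <- matrix(rnorm(80), 20, 4)
  co <- npx_cohort(X, rep(c("A", "B", "C", "H"), each = 5))
  expect_message(
    m <- two_stage(co, tax, first_stage = node_spec("ridge"),
                   second_stage = list(C1 = node_spec("ridge")),
                   oversample = FALSE, seed = 1),
    "pass-through")
  expect_equal(m$first_classes, c("C1", "C2", "H"))
  expect_true(isTRUE(m$second_stage$C2$passthrough))
  expect_false(isTRUE(m$second_stage$C1$passthrough))
  expect_equal(m$label_order, c("A", "B", "C", "H"))

  co_bad <- npx_cohort(X, replace(co$labels, 1, "XYZ"))
  expect_error(two_stage(co_bad, tax, oversample = FALSE), "XYZ")
})

test_that("the product mixture reproduces hand-computed probabilities", {
  # class-prior (dummy) nodes give controlled stage probabilities:
  # P_f = (0.6, 0.4) over {C1, C2}; g_1 = (0.5, 0.5); C2 passes through to C
  tax <- taxonomy(list(C1 = c("A", "B"), C2 = "C"))
  set.seed(2)
  X <- matrix(rnorm(40), 10, 4)
  co <- npx_cohort(X, rep(c("A", "B", "C"), c(3, 3, 4)))
  m <- suppressMessages(two_stage(
    co, tax, first_stage = node_spec("dummy"),
    second_stage = list(C1 = node_spec("dummy")),
    oversample = FALSE, seed = 1))
  pr <- predict_full(m, matrix(0, 2, 4))
  expect_equal(unname(pr[1, ]), c(0.30, 0.30, 0.40))
  expect_equal(colnames(pr), c("A", "B", "C"))
  expect_equal(rowSums(pr), c(1, 1), ignore_attr = TRUE)

  # one-hot (hard-routing) first stage: P = P_f one-hot times g
  m1 <- suppressMessages(two_stage(
    co, tax, first_stage = node_spec("dummy", prob_rule = "onehot"),
    second_stage = list(C1 = node_spec("dummy")),
    oversample = FALSE, seed = 1))
  pr1 <- predict_full(m1, matrix(0, 2, 4))
  expect_equal(unname(pr1[1, ]), c(0.5, 0.5, 0))
  # exact tie between A and B resolved by fixed label order
  expect_equal(predict(m1, matrix(0, 2, 4)), c("A", "A"))
})

test_that("probability rows sum to one and decompose by category", {
  co <- demo_cohort(seed = 31)
  sp <- stratified_split(co, 0.7, seed = 1)
  m <- suppressWarnings(two_stage(sp$train, demo_taxonomy(), seed = 2))
  pr <- predict_full(m, sp$test)
  expect_true(all(abs(rowSums(pr) - 1) < 1e-9))
  # summing member entries reproduces the first-stage category probability
  pf <- node_probs(m$first_stage, sp$test$npx)
  expect_equal(unname(rowSums(pr[, c("AML", "CLL")])),
               unname(pf[, "blood"]), tolerance = 1e-12)
  expect_equal(unname(pr[, "HEALTHY"]), unname(pf[, "HEALTHY"]),
               tolerance = 1e-12)
})

test_that("one-hot routing equals the explicit two-step composition", {
  co <- demo_cohort(seed = 32)
  sp <- stratified_split(co, 0.7, seed = 1)
  tax <- demo_taxonomy()
  m <- suppressWarnings(two_stage(
    sp$train, tax,
    first_stage = node_spec("perceptron", prob_rule = "onehot"),
    seed = 5))
  pred <- predict(m, sp$test$npx)
  # oracle: classify the category, then classify within the category
  pf <- node_probs(m$first_stage, sp$test$npx)
  cat_hat <- colnames(pf)[max.col(pf, ties.method = "first")]
  oracle <- character(length(cat_hat))
  for (i in seq_along(cat_hat)) {
    cl <- cat_hat[i]
    if (cl %in% names(m$second_stage)) {
      g <- m$second_stage[[cl]]
      pg <- node_probs(g$node, sp$test$npx[i, , drop = FALSE])
      oracle[i] <- colnames(pg)[which.max(pg)]
    } else {
      oracle[i] <- cl
    }
  }
  expect_identical(pred, oracle)
})

test_that("predictions are row-wise and reject mismatched features", {
  co <- demo_cohort(seed = 33, n = c(AML = 8, CLL = 8, BD = 8, SZ = 8,
                                     HEALTHY = 8))
  m <- suppressWarnings(two_stage(co, demo_taxonomy(), oversample = FALSE,
                                  seed = 2))
  X <- co$npx[1:6, ]
  shuf <- c(4, 2, 6, 1, 3, 5)
  expect_identical(predict(m, X)[shuf], predict(m, X[shuf, ]))
  expect_error(predict_full(m, X[, 1:3]), "feature mismatch")
})

test_that("binary restriction renormalizes without retraining", {
  pr <- rbind(c(HEALTHY = 0.1, BRC = 0.3, OTHER = 0.6),
              c(HEALTHY = 0.2, BRC = 0.0, OTHER = 0.8),
              c(HEALTHY = 0.0, BRC = 0.0, OTHER = 1.0))
  expect_warning(b <- restrict_binary(pr, "HEALTHY", "BRC"), "0.5")
  expect_equal(unname(b[1, ]), c(0.25, 0.75))
  expect_equal(unname(b[2, ]), c(1.0, 0.0))
  expect_equal(unname(b[3, ]), c(0.5, 0.5))
  expect_true(all(abs(rowSums(b) - 1) < 1e-12))
  expect_error(restrict_binary(pr, "HEALTHY", "NOPE"), "NOPE")
})

test_that("feature-restricted refits replicate the training protocol", {
  co <- demo_cohort(seed = 34)
  tax <- demo_taxonomy()
  sp <- stratified_split(co, 0.7, seed = 1)
  m_full <- suppressWarnings(two_stage(sp$train, tax, seed = 9))
  m_all <- suppressWarnings(restrict_to_features(
    sp$train, tax, features = colnames(co$npx), seed = 9))
  expect_identical(predict(m_full, sp$test$npx),
                   predict(m_all, sp$test$npx))
  expect_error(restrict_to_features(sp$train, tax, features = "NOPE"),
               "NOPE")
  expect_error(restrict_to_features(sp$train, tax, features = character()),
               "features")
  # markers carry all the signal: restriction to them barely loses accuracy
  markers <- colnames(co$npx)[1:11]
  m_mark <- suppressWarnings(restrict_to_features(sp$train, tax,
                                                  features = markers,
                                                  seed = 9))
  acc_full <- mean(predict(m_full, sp$test$npx) == sp$test$labels)
  acc_mark <- mean(predict(m_mark, sp$test$npx[, markers]) == sp$test$labels)
  expect_gt(acc_mark, acc_full - 0.1)
})

test_that("candidate ranking is CV-based, ordered, and deterministic", {
  co <- demo_cohort(seed = 35, n = c(AML = 15, CLL = 15, BD = 15, SZ = 15,
                                     HEALTHY = 15))
  cands <- list(ridge = node_spec("ridge"),
                dummy = node_spec("dummy"),
                perceptron = node_spec("perceptron", epochs = 10))
  r <- select_classifier(co$npx, co$labels, cands, n_folds = 3, seed = 4)
  expect_equal(r$rank, 1:3)
  expect_true(all(diff(r$mean_cv_f1) <= 0))
  expect_equal(r$candidate[3], "dummy")  # prior guessing ranks last
  r2 <- select_classifier(co$npx, co$labels, cands, n_folds = 3, seed = 4)
  expect_identical(r, r2, ignore_attr = TRUE)

  single <- select_classifier(co$npx, co$labels,
                              list(dummy = node_spec("dummy")),
                              n_folds = 3, seed = 1)
  expect_equal(single$candidate, "dummy")
  expect_equal(single$rank, 1L)

  tiny <- npx_cohort(co$npx[1:17, ], c(rep("A", 15), "B", "B"))
  expect_error(select_classifier(tiny$npx, tiny$labels, cands, n_folds = 3),
               "B")
})

test_that("linearly separable classes give perfect CV F1 for linear models", {
  tax <- taxonomy(list(g = c("A", "B")))
  cfg <- sim_config(c(A = 20, B = 20), tax, n_proteins = 10,
                    disease_markers = list(
                      A = data.frame(protein = 1, shift = 12)),
                    noise_sd = 1, seed = 8)
  co <- simulate_cohort(cfg)
  r <- select_classifier(co$npx, co$labels,
                         list(ridge = node_spec("ridge"),
                              logistic = node_spec("logistic")),
                         n_folds = 5, seed = 2)
  expect_true(all(r$mean_cv_f1 == 1))
})
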
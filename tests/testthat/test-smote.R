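# Geometry used below: 1-D coordinates chosen so the k nearest neighbors of
# the probed minority point are known by construction.

test_that("danger/noise/safe regions follow the k/2 <= m < k rule", {
  # probe at 0 with k = 4 nearest at 1, 2, 3, 4; m = 2 majority -> danger
  X <- matrix(c(0, 1, 2, 3, 4, 100, 101), ncol = 1)
  y <- c("min", "maj", "maj", "min", "min", "maj", "min")
  r <- assign_minority_regions(X, y, "min", k = 4)
  expect_equal(r$region[r$index == 1], "danger")
  expect_equal(r$m[r$index == 1], 2L)

  # m = k -> noise, excluded from synthesis
  y2 <- c("min", "maj", "maj", "maj", "maj", "min", "min")
  r2 <- assign_minority_regions(X, y2, "min", k = 4)
  expect_equal(r2$region[r2$index == 1], "noise")

  # m = 0 -> safe
  y3 <- c("min", "min", "min", "min", "min", "maj", "maj")
  r3 <- assign_minority_regions(X, y3, "min", k = 4)
  expect_equal(r3$region[r3$index == 1], "safe")

  # real-valued k/2 boundary: k = 5 puts m = 3 and m = 4 in danger, m = 2 safe
  X5 <- matrix(c(0, 1, 2, 3, 4, 5, 50, 51), ncol = 1)
  y5 <- c("min", "maj", "maj", "maj", "min", "min", "min", "maj")
  r5 <- assign_minority_regions(X5, y5, "min", k = 5)
  expect_equal(r5$m[r5$index == 1], 3L)
  expect_equal(r5$region[r5$index == 1], "danger")

  expect_error(assign_minority_regions(X, y, "min", k = 6), "k")
  expect_error(assign_minority_regions(X, y, "min", k = 0), "k")
})

test_that("interpolation stays on the seed-partner segment", {
  expect_equal(synthesize_sample(c(1, 2), c(5, 6), 0), c(1, 2))
  expect_equal(synthesize_sample(c(1, 2), c(5, 6), 1), c(5, 6))
  expect_equal(synthesize_sample(c(0, 0), c(2, 4), 0.5), c(1, 2))
  expect_error(synthesize_sample(c(0, 0), c(2, 4), 1.5), "lambda")
  expect_error(synthesize_sample(c(0, 0), c(2, 4, 6), 0.5), "length")
})

make_imbalanced <- function(seed, n_maj = 50, n_min = 10) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_maj * 2), n_maj),
             matrix(rnorm(n_min * 2, mean = 1.2), n_min))
  list(X = X, y = rep(c("maj", "min"), c(n_maj, n_min)))
}

test_that("oversampling balances classes and logs exact provenance", {
  d <- make_imbalanced(1)
  aug <- borderline_smote(d$X, d$y, k = 5, seed = 42)
  expect_equal(as.numeric(table(aug$y)), c(50, 50))
  # original rows are preserved unchanged, synthetic rows appended
  expect_equal(aug$X[seq_len(60), ], unname(d$X), ignore_attr = TRUE)
  expect_equal(nrow(aug$provenance), 40L)
  # every synthetic row is the logged affine combination, exactly
  for (i in seq_len(nrow(aug$provenance))) {
    p <- aug$provenance[i, ]
    expected <- d$X[p$seed_index, ] +
      p$lambda * (d$X[p$partner_index, ] - d$X[p$seed_index, ])
    expect_equal(unname(aug$X[60 + i, ]), unname(expected))
    expect_equal(d$y[p$seed_index], "min")
    expect_equal(d$y[p$partner_index], "min")  # minority-only partner pool
    expect_true(p$lambda >= 0 && p$lambda <= 1)
  }
  # seed indices are danger-region points
  regions <- assign_minority_regions(d$X, d$y, "min", k = 5)
  danger <- regions$index[regions$region == "danger"]
  expect_true(all(aug$provenance$seed_index %in% danger))
})

test_that("oversampling is deterministic and respects fallbacks", {
  d <- make_imbalanced(2)
  a1 <- borderline_smote(d$X, d$y, k = 5, seed = 7)
  a2 <- borderline_smote(d$X, d$y, k = 5, seed = 7)
  expect_identical(a1$X, a2$X)
  expect_identical(a1$provenance, a2$provenance)

  # fully separated minority cluster: no danger points -> unchanged + warning
  X <- rbind(matrix(rnorm(80), 40), matrix(rnorm(20, mean = 50), 10))
  y <- rep(c("maj", "min"), c(40, 10))
  expect_warning(res <- borderline_smote(X, y, k = 5, seed = 1),
                 "no danger-region")
  expect_equal(nrow(res$X), 50L)

  expect_error(borderline_smote(d$X, rep("one", nrow(d$X)), k = 5),
               "2 classes")
})

test_that("multiclass oversampling brings every class to the majority count", {
  set.seed(3)
  X <- rbind(matrix(rnorm(120), 60),
             matrix(rnorm(24, 1), 12),
             matrix(rnorm(16, -1), 8))
  y <- rep(c("big", "mid", "small"), c(60, 12, 8))
  aug <- borderline_smote(X, y, k = 5, seed = 5)
  expect_equal(as.numeric(table(aug$y)[c("big", "mid", "small")]),
               rep(60, 3))
})

test_that("oversampling raises minority recall on overlapping classes", {
  # clustered majority, scattered minority near the boundary; a linear
  # classifier should recover minority recall after oversampling
  delta <- vapply(1:20, function(s) {
    set.seed(s)
    n_maj <- 80; n_min <- 12
    Xtr <- rbind(matrix(rnorm(n_maj * 2), n_maj),
                 matrix(rnorm(n_min * 2, mean = 1.0, sd = 1.4), n_min))
    ytr <- rep(c("maj", "min"), c(n_maj, n_min))
    Xte <- rbind(matrix(rnorm(200 * 2), 200),
                 matrix(rnorm(60 * 2, mean = 1.0, sd = 1.4), 60))
    yte <- rep(c("maj", "min"), c(200, 60))
    recall_min <- function(X, y) {
      fit <- fit_node(node_spec("ridge"), X, y, seed = s)
      pr <- node_probs(fit, Xte)
      pred <- fit$levels[max.col(pr, ties.method = "first")]
      mean(pred[yte == "min"] == "min")
    }
    aug <- suppressWarnings(borderline_smote(Xtr, ytr, k = 5, seed = s))
    recall_min(aug$X, aug$y) - recall_min(Xtr, ytr)
  }, numeric(1))
  expect_gt(mean(delta), 0)
})
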
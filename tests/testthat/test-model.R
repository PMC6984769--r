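# Small shared benchmark: 60 pairs, CGR features (40 columns) keep the
# forest fits cheap; learnability at scale is exercised separately.
sim60 <- generate_pairs(synthetic_config(n_pairs = 60, seed = 21))
mat60 <- build_matrix(sim60$pairs, sim60$proteins, sim60$rnas, "CGR")

test_that("training is seeded-deterministic and validates its inputs", {
  m1 <- train_rf(mat60, ntree = 300, seed = 4)
  m2 <- train_rf(mat60, ntree = 300, seed = 4)
  p1 <- predict(m1, mat60)
  p2 <- predict(m2, mat60)
  expect_identical(p1, p2)
  expect_true(all(p1$score >= 0 & p1$score <= 1))
  expect_identical(p1$class, as.integer(p1$score >= 0.5))
  # training accuracy on balanced data it has seen clears the sanity floor
  expect_gte(mean(p1$class == mat60$labels), 0.5)

  expect_error(train_rf(mat60$x[1:20, ], rep(1L, 20), ntree = 300),
               "single class")
  expect_error(train_rf(mat60, ntree = 300, mtry = 41), "mtry")
  expect_error(train_rf(mat60$x, NULL, ntree = 300), "labels")
})

test_that("prediction refuses matrices from a different feature set", {
  model <- train_rf(mat60, ntree = 300, seed = 4)
  other <- build_matrix(sim60$pairs[1:3, ], sim60$proteins, sim60$rnas, "AAC+NC")
  expect_error(predict(model, other), "feature mismatch")
  # identical rows get identical scores
  x3 <- mat60$x[c(1, 1, 1), ]
  s <- predict(model, x3)$score
  expect_equal(s, rep(s[1], 3))
})

test_that("stratified folds partition the samples and preserve class balance", {
  set.seed(41)
  for (i in 1:10) {
    n_pos <- sample(10:40, 1)
    n_neg <- sample(10:40, 1)
    labels <- sample(c(rep(1L, n_pos), rep(0L, n_neg)))
    fold <- stratified_folds(labels, k = 10, seed = i)
    expect_setequal(fold, 1:10)                      # union = all folds
    expect_length(fold, n_pos + n_neg)               # each sample exactly once
    for (cls in 0:1) {
      sizes <- table(fold[labels == cls])
      expect_lte(diff(range(sizes)), 1)
    }
  }
  expect_error(stratified_folds(rep(0:1, 4), k = 10), "fewer samples")
})

test_that("cross-validation pools out-of-fold counts and reproduces under a seed", {
  cv1 <- cross_validate(mat60, ntree = 300, seed = 5)
  cv2 <- cross_validate(mat60, ntree = 300, seed = 5)
  expect_identical(cv1$scores, cv2$scores)
  expect_equal(cv1$pooled, cv2$pooled)
  expect_length(cv1$per_fold, 10L)
  pooled_counts <- Reduce(`+`, lapply(cv1$per_fold, `[[`, "counts"))
  expect_equal(sum(pooled_counts), nrow(mat60$x))    # every sample held out once
  expect_equal(cv1$pooled$counts, pooled_counts)
  expect_equal(cv1$pooled$AUC, auc_rank(cv1$scores, mat60$labels))

  expect_error(cross_validate(mat60$x[1:9, ], mat60$labels[1:9], folds = 10),
               "samples per class")
})

test_that("grid search honours the tie-break rules", {
  # one grid point: returned as-is
  g1 <- grid_search(mat60, ntree_grid = 300, mtry_grid = 6, folds = 10, seed = 6)
  expect_equal(g1$best, list(ntree = 300L, mtry = 6L))

  # a perfectly separated single informative feature gives ACC = 1 at
  # every grid point, so ties resolve to the smallest ntree then mtry
  x <- cbind(sig = c(rep(0, 20), rep(1, 20)),
             noise = rep(c(0.1, 0.9), 20))
  colnames(x) <- c("sig", "noise")
  y <- c(rep(0L, 20), rep(1L, 20))
  gs <- grid_search(x, y, ntree_grid = c(400, 300), mtry_grid = c(2, 1),
                    folds = 10, seed = 6)
  expect_true(all(gs$table$ACC == 1))
  expect_equal(gs$best, list(ntree = 300L, mtry = 1L))

  expect_error(grid_search(mat60, ntree_grid = integer(0)), "empty")
  expect_error(grid_search(mat60, ntree_grid = 300, mtry_grid = 100), "mtry grid")
})

test_that("default mtry grid is log-spaced within range and includes sqrt(n)", {
  for (n in c(1, 24, 40, 599, 639, 663)) {
    g <- default_mtry_grid(n)
    expect_true(all(g >= 1 & g <= n))
    expect_true(floor(sqrt(n)) %in% g || n == 1)
    expect_identical(g, sort(unique(g)))
  }
})

test_that("models survive a save/load round trip", {
  model <- train_rf(mat60, ntree = 300, seed = 4)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(model, f)
  back <- load_model(f)
  expect_identical(predict(back, mat60), predict(model, mat60))
  expect_identical(back$feature_set, "CGR")
})
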
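test_that("SMOTE restores exact class parity with convex synthetic rows", {
  set.seed(20)
  x <- matrix(rnorm(100 * 4), 100, 4,
              dimnames = list(NULL, paste0("F", 1:4)))
  y <- rep(c(0L, 1L), times = c(70, 30))
  out <- smote_oversample(x, y, k_neighbors = 5, seed = 1)
  expect_equal(sum(out$synthetic), 40)
  expect_equal(as.integer(table(out$outcome)), c(70L, 70L))
  # every synthetic coordinate lies between its two parents
  synth <- out$features[out$synthetic, , drop = FALSE]
  for (i in seq_len(nrow(synth))) {
    p1 <- x[out$parents[i, 1], ]
    p2 <- x[out$parents[i, 2], ]
    expect_true(all(synth[i, ] >= pmin(p1, p2) - 1e-12 &
                      synth[i, ] <= pmax(p1, p2) + 1e-12))
  }
  # identical minority points can only produce themselves
  x2 <- rbind(x[1:70, ], matrix(2, 10, 4))
  colnames(x2) <- colnames(x)
  y2 <- rep(c(0L, 1L), times = c(70, 10))
  out2 <- smote_oversample(x2, y2, k_neighbors = 3, seed = 2)
  expect_true(all(out2$features[out2$synthetic, ] == 2))
  expect_error(smote_oversample(x2, y2, k_neighbors = 11), "k_neighbors")
})

test_that("a random forest separates a separable toy perfectly", {
  d <- toy_separable(n = 100)
  m <- tune_and_fit("RF", d$x, d$y, seed = 3)
  expect_equal(roc_auc(predict_scores(m, d$x), d$y), 1.0)
})

test_that("fits and predictions are deterministic under the seed", {
  d <- toy_separable(n = 120, seed = 6)
  for (cl in c("RF", "XGBoost", "PR", "SVM")) {
    m1 <- tune_and_fit(cl, d$x, d$y, seed = 77, grid = "fast")
    m2 <- tune_and_fit(cl, d$x, d$y, seed = 77, grid = "fast")
    expect_equal(m1$hyperparameters, m2$hyperparameters)
    expect_identical(predict_scores(m1, d$x), predict_scores(m2, d$x))
  }
})

test_that("all classifiers emit probabilities in [0, 1]", {
  d <- toy_separable(n = 90, seed = 7)
  new <- toy_separable(n = 30, seed = 8)$x
  for (cl in classifiers()) {
    m <- tune_and_fit(cl, d$x, d$y, seed = 5, grid = "fast")
    sc <- predict_scores(m, new)
    expect_true(all(sc >= 0 & sc <= 1))
    expect_length(sc, 30)
  }
})

test_that("stepwise regression refuses wide feature sets", {
  set.seed(9)
  x <- matrix(rnorm(100 * 60), 100, 60,
              dimnames = list(NULL, sprintf("F%03d", 1:60)))
  y <- rep(0:1, 50)
  expect_error(tune_and_fit("LSR", x, y, seed = 1), "refused")
})

test_that("1-nearest-neighbour echoes the label of a duplicated point", {
  d <- toy_separable(n = 50, seed = 11)
  m <- tune_and_fit("KNN", d$x, d$y, grid = data.frame(k = 1), seed = 2)
  sc <- predict_scores(m, d$x[c(1, 2), , drop = FALSE])
  expect_equal(sc, as.numeric(d$y[c(1, 2)]))
})

test_that("probability mapping preserves the SVM ranking", {
  d <- toy_separable(n = 150, seed = 12)
  m <- tune_and_fit("SVM", d$x, d$y, seed = 4, grid = "fast")
  sc <- predict_scores(m, d$x)
  # plogis is monotone: AUC from probabilities equals AUC from logits
  expect_equal(roc_auc(sc, d$y), roc_auc(qlogis(pmin(pmax(sc, 1e-12),
                                                     1 - 1e-12)), d$y))
  expect_gt(roc_auc(sc, d$y), 0.99)
})

test_that("importance is exposed exactly for PR, RF, XGBoost and LSR", {
  set.seed(13)
  n <- 200
  y <- rep(0:1, each = n / 2)
  x <- cbind(signal = y + rnorm(n, sd = 0.3),
             noise1 = rnorm(n), noise2 = rnorm(n),
             const = rep(1, n))
  for (cl in c("PR", "RF", "XGBoost", "LSR")) {
    m <- tune_and_fit(cl, x, y, seed = 21, grid = "fast")
    imp <- extract_importance(m)
    expect_equal(imp$feature[1], "signal")
    expect_equal(imp$importance[imp$feature == "const"], 0)
    expect_true(all(diff(imp$importance) <= 1e-12))
  }
  for (cl in c("KNN", "SVM")) {
    m <- tune_and_fit(cl, x, y, seed = 21, grid = "fast")
    expect_error(extract_importance(m), "importance")
  }
})

test_that("single-feature training folds are fitted without error", {
  set.seed(14)
  n <- 120
  y <- rep(0:1, each = n / 2)
  x <- matrix(y + rnorm(n, sd = 0.5), ncol = 1,
              dimnames = list(NULL, "only"))
  for (cl in c("PR", "RF", "XGBoost", "KNN", "SVM")) {
    m <- tune_and_fit(cl, x, y, seed = 3, grid = "fast")
    expect_gt(roc_auc(predict_scores(m, x), y), 0.7)
    if (cl %in% c("PR", "RF", "XGBoost")) {
      expect_equal(extract_importance(m)$feature, "only")
    }
  }
})

test_that("missing validation features raise a named error", {
  d <- toy_separable(n = 60, seed = 15)
  m <- tune_and_fit("RF", d$x, d$y, seed = 1, grid = "fast")
  expect_error(predict_scores(m, d$x[, 1, drop = FALSE]), "f2")
})
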
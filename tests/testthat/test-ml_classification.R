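test_that("random oversampling balances classes exactly", {
  # the canonical imbalance: 31 cases vs 46 controls -> 46/46
  y <- rep(c(1, 0), c(31, 46))
  X <- data.frame(x = seq_along(y))
  os <- random_oversample(X, y, seed = 1)
  expect_equal(unname(table(os$labels)), c(46L, 46L), ignore_attr = TRUE)
  expect_true(all(os$features$x %in% X$x))
  # already balanced input is unchanged
  y2 <- rep(0:1, each = 10)
  os2 <- random_oversample(data.frame(x = 1:20), y2, seed = 1)
  expect_identical(os2$index, 1:20)
  # a singleton minority is duplicated up to the majority size
  y3 <- c(rep(0, 9), 1)
  os3 <- random_oversample(data.frame(x = 1:10), y3, seed = 1)
  expect_equal(sum(os3$labels == 1), 9)
  expect_true(all(os3$features$x[os3$labels == 1] == 10))
  expect_error(random_oversample(data.frame(x = 1:5), rep(1, 5)),
               "both classes")
})

test_that("weighted recall equals accuracy for arbitrary predictions", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(10:60, 1)
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(truth)) < 2) next
    pred <- rbinom(n, 1, 0.5)
    m <- weighted_metrics(pred, truth)
    expect_equal(unname(m["recall"]), unname(m["accuracy"]), tolerance = 1e-12)
  }
  perfect <- weighted_metrics(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(unname(perfect), rep(100, 4))
  const <- weighted_metrics(rep(1, 10), rep(0:1, 5))
  expect_equal(unname(const["accuracy"]), 50)
  expect_equal(unname(const["recall"]), 50)
})

test_that("normalized confusion matrix is row-stochastic arithmetic", {
  truth <- rep(c(1, 0), c(10, 10))
  pred <- c(rep(1, 7), rep(0, 3), rep(1, 2), rep(0, 8))
  cm <- confusion_matrix_normalized(pred, truth)
  expect_equal(cm["1", ], c("0" = 0.3, "1" = 0.7))
  expect_equal(cm["0", ], c("0" = 0.8, "1" = 0.2))
  expect_equal(unname(rowSums(cm)), c(1, 1))
  id <- confusion_matrix_normalized(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(unname(id), diag(2))
  allpos <- confusion_matrix_normalized(rep(1, 4), c(0, 0, 1, 1))
  expect_equal(unname(allpos), matrix(c(0, 0, 1, 1), 2, 2))
  expect_error(confusion_matrix_normalized(c(0, 1), c(1, 1)), "both classes")
})

test_that("cross-validation is deterministic and leakage-free", {
  tab <- simulate_feature_table(15, c(a = 2, b = 1), seed = 9)
  specs <- list(classifier_spec("LDA"), classifier_spec("NB"))
  r1 <- run_cv(tab$features, tab$labels, specs, k = 3, seed = 5)
  r2 <- run_cv(tab$features, tab$labels, specs, k = 3, seed = 5)
  expect_identical(r1$classifiers$LDA$fold_metrics,
                   r2$classifiers$LDA$fold_metrics)
  expect_identical(r1$classifiers$NB$confusion, r2$classifiers$NB$confusion)
  # every original sample is predicted exactly once on an untouched test fold
  expect_length(r1$classifiers$LDA$predictions, length(tab$labels))
  expect_equal(sort(unique(r1$fold)), 1:3)
  # oversampling only ever draws training rows (structural leakage audit)
  y <- rep(c(0, 1), c(20, 8))
  fold_ids <- seq_along(y)
  os <- random_oversample(data.frame(i = fold_ids), y, seed = 2)
  expect_true(all(os$features$i %in% fold_ids))
  sub <- c(1:4, 16:19)  # four samples per class
  expect_error(run_cv(tab$features[sub, ], tab$labels[sub], specs, k = 5),
               "smaller k")
})

test_that("paired fold test matches the textbook formula", {
  tab <- simulate_feature_table(15, c(a = 2), seed = 3)
  r <- run_cv(tab$features, tab$labels,
              list(classifier_spec("LDA"), classifier_spec("NB")),
              k = 5, seed = 2)
  pt <- paired_fold_test(r, "LDA", "NB")
  a <- r$classifiers$LDA$fold_metrics[, "accuracy"]
  b <- r$classifiers$NB$fold_metrics[, "accuracy"]
  if (sd(a - b) > 0) {
    ref <- t.test(a, b, paired = TRUE)
    expect_equal(pt$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(pt$p, ref$p.value, tolerance = 1e-12)
    expect_equal(pt$df, 4)
  }
  same <- paired_fold_test(r, "LDA", "LDA")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("grid search selects sensible hyperparameters", {
  tab <- simulate_feature_table(30, c(a = 2.5, b = 2), seed = 4)
  spec <- classifier_spec("KNN", data.frame(k = c(2, 5, 15)))
  r <- run_cv(tab$features, tab$labels, list(spec), k = 3, seed = 1)
  ks <- vapply(r$classifiers$KNN$chosen, function(ch) ch$k, numeric(1))
  expect_true(all(ks %in% c(2, 5, 15)))
  expect_gt(r$classifiers$KNN$mean["accuracy"], 85)
})

test_that("oversample-before-CV is available but flagged as permissive", {
  tab <- simulate_feature_table(12, c(a = 1), seed = 6)
  y <- tab$labels
  y[1:6] <- 1  # make it imbalanced 6/18
  r <- run_cv(tab$features, y, list(classifier_spec("LDA")), k = 3,
              seed = 3, oversample_before_cv = TRUE)
  expect_length(r$classifiers$LDA$predictions, 2 * max(table(y)))
})
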
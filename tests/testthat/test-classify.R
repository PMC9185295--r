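test_that("clip feature aggregation is mean by default, sum on request", {
  f <- c(0, 2, 4)
  expect_equal(aggregate_clip_feature(list(f)), f)
  expect_equal(aggregate_clip_feature(list(f, f)), f)  # idempotent mean
  expect_equal(aggregate_clip_feature(list(c(0, 2), c(2, 0))), c(1, 1))
  expect_equal(aggregate_clip_feature(list(c(0, 2), c(2, 0)), "sum"), c(2, 2))
  expect_error(aggregate_clip_feature(list()), "no features")
  expect_error(aggregate_clip_feature(list(1:2, 1:3)), "unequal")
})

test_that("LOSO folds partition clips with subject-disjoint sides", {
  df <- data.frame(clip_id = paste0("c", 1:4), path = ".",
                   subject = c("A", "A", "B", "C"),
                   label = c("x", "y", "x", "y"))
  idx <- dataset_index(df)
  folds <- loso_split(idx)
  expect_length(folds, 3)
  expect_equal(vapply(folds, function(f) length(f$test), integer(1)),
               c(2L, 1L, 1L))
  # subject order = first-appearance order
  expect_equal(vapply(folds, `[[`, character(1), "subject"),
               c("A", "B", "C"))
  for (f in folds) {
    expect_setequal(c(f$train, f$test), df$clip_id)
    expect_length(intersect(f$train, f$test), 0)
    test_subj <- df$subject[df$clip_id %in% f$test]
    train_subj <- df$subject[df$clip_id %in% f$train]
    expect_length(intersect(test_subj, train_subj), 0)
  }
  expect_error(loso_split(dataset_index(df[df$subject == "A", ])),
               "2 subjects")
})

test_that("linear SVM separates separable clouds and flags bad folds", {
  set.seed(12)
  a <- matrix(rnorm(40, mean = 0), 20, 2)
  b <- matrix(rnorm(40, mean = 6), 20, 2)
  x <- rbind(a, b)
  y <- rep(c("lo", "hi"), each = 20)
  pred <- fit_predict_linear_svm(x, y, x)
  expect_equal(pred, y)  # 100% training accuracy on separable data
  # a test point deep inside one class gets that class
  expect_equal(fit_predict_linear_svm(x, y, matrix(c(6, 6), 1, 2)), "hi")
  expect_error(fit_predict_linear_svm(a, rep("lo", 20), a), "single class")
})

test_that("3-class Gaussian blobs classify above chance under LOSO", {
  set.seed(13)
  centers <- matrix(c(0, 0, 4, 0, 0, 4), 3, 2, byrow = TRUE)
  n_sub <- 5
  rows <- list(); feats <- list()
  for (s in seq_len(n_sub)) for (cl in 1:3) for (r in 1:2) {
    id <- sprintf("s%d_c%d_%d", s, cl, r)
    rows[[id]] <- data.frame(clip_id = id, path = ".",
                             subject = paste0("s", s),
                             label = paste0("c", cl))
    feats[[id]] <- centers[cl, ] + rnorm(2, sd = 0.8)
  }
  idx <- dataset_index(do.call(rbind, rows))
  X <- do.call(rbind, feats)
  labs <- stats::setNames(idx$entries$label, idx$entries$clip_id)
  truth <- character(0); pred <- character(0)
  for (f in loso_split(idx)) {
    p <- fit_predict_linear_svm(X[f$train, , drop = FALSE], labs[f$train],
                                X[f$test, , drop = FALSE])
    truth <- c(truth, labs[f$test]); pred <- c(pred, p)
  }
  acc <- mean(truth == pred)
  expect_gt(acc, 1 / 3 + 0.2)  # well above chance
})

test_that("metrics match hand-computed per-class counting", {
  # perfect 2-class diagonal
  m <- compute_metrics(diag(c(4, 6)))
  expect_equal(m$accuracy, 1); expect_equal(m$macro_f1, 1)
  expect_equal(m$macro_recall, 1)
  # truth-major [[5,5],[0,10]]: hand-derived from TP/FP/FN counts
  cm <- matrix(c(5, 5, 0, 10), 2, 2, byrow = TRUE)
  m2 <- suppressWarnings(compute_metrics(cm))
  expect_equal(m2$accuracy, 0.75)
  expect_equal(m2$per_class$recall, c(0.5, 1.0))
  expect_equal(m2$macro_recall, 0.75)
  expect_equal(m2$per_class$precision, c(1.0, 2 / 3))
  expect_equal(m2$macro_f1, (2 * 1 * 0.5 / 1.5 + 2 * (2 / 3) * 1 / (5 / 3)) / 2,
               tolerance = 1e-12)
  # all predictions in one class, balanced 3-class truth
  cm3 <- matrix(0, 3, 3); cm3[, 1] <- 5
  m3 <- suppressWarnings(compute_metrics(cm3))
  expect_equal(m3$accuracy, 1 / 3)
  expect_equal(m3$macro_recall, 1 / 3)
  # the printed-formula variant (precision-style) is also reported
  expect_equal(m3$macro_precision, mean(c(5 / 15, 0, 0)))
  expect_error(compute_metrics(matrix(c(-1, 0, 0, 1), 2)), "non-negative")
})

test_that("metrics against a brute-force per-class counter on random data", {
  set.seed(14)
  classes <- c("p", "n", "s")
  truth <- sample(classes, 60, replace = TRUE)
  pred <- sample(classes, 60, replace = TRUE)
  cm <- confusion_matrix(truth, pred, classes)
  expect_equal(sum(cm), 60)
  m <- suppressWarnings(compute_metrics(cm))
  # brute force from the raw label vectors
  accs <- mean(truth == pred)
  expect_equal(m$accuracy, accs)
  rec <- sapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl); fn <- sum(truth == cl & pred != cl)
    if (tp + fn == 0) 0 else tp / (tp + fn)
  })
  expect_equal(m$macro_recall, mean(rec))
  prec <- sapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl); fp <- sum(truth != cl & pred == cl)
    if (tp + fp == 0) 0 else tp / (tp + fp)
  })
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  expect_equal(m$macro_f1, mean(f1))
})
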
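test_that("the confusion matrix counts by true row and predicted column", {
  cm <- confusion(c(1, 2, 3), c(1, 2, 3), n_classes = 3)
  expect_equal(unname(diag(unclass(cm))), c(1, 1, 1))
  expect_equal(sum(cm), 3)

  cm2 <- confusion(c(1, 1, 2), c(1, 2, 2), n_classes = 2)
  m1 <- metrics(cm2, 1)
  expect_equal(unname(m1[c("TP", "FN", "FP", "TN")]), c(1, 1, 0, 1))

  set.seed(51)
  yt <- sample(1:6, 180, replace = TRUE)
  yp <- sample(1:6, 180, replace = TRUE)
  expect_equal(sum(confusion(yt, yp)), 180)
  expect_error(confusion(1:3, 1:2), "equal length")
})

test_that("accuracy, sensitivity and FPR are the direct count ratios", {
  # worked one-vs-rest example: TP=29, FN=1, FP=2, TN=148
  yt <- c(rep(1, 30), rep(2, 150))
  yp <- c(rep(1, 29), 2, rep(1, 2), rep(2, 148))
  m <- metrics(confusion(yt, yp, n_classes = 2), 1)
  expect_equal(unname(m[c("TP", "FN", "FP", "TN")]), c(29, 1, 2, 148))
  expect_equal(m[["ACC"]], 177 / 180)
  expect_equal(m[["TPR"]], 29 / 30)
  expect_equal(m[["FPR"]], 2 / 150)
  expect_equal(m[["specificity"]], 1 - 2 / 150)

  perfect <- metrics(confusion(rep(1:2, 5), rep(1:2, 5), n_classes = 2), 1)
  expect_equal(perfect[["ACC"]], 1)
  expect_equal(perfect[["FPR"]], 0)

  # class absent entirely: 0/0 reported as NA sentinel
  absent <- metrics(confusion(rep(1, 4), rep(1, 4), n_classes = 6), 3)
  expect_true(is.na(absent[["TPR"]]))
})

test_that("OVR one-vs-rest counts sum back to the confusion-matrix trace", {
  set.seed(52)
  yt <- sample(1:6, 120, replace = TRUE)
  yp <- ifelse(runif(120) < 0.7, yt, sample(1:6, 120, replace = TRUE))
  cm <- confusion(yt, yp)
  tps <- vapply(1:6, function(k) metrics(cm, k)[["TP"]], 0)
  expect_equal(sum(tps), sum(diag(unclass(cm)[, 1:6])))
})

test_that("the ROC sweep equals the pairwise-comparison oracle", {
  # perfect separation and uninformative scores first
  yt <- rep(c(1, 2), each = 10)
  expect_equal(ovr_roc(c(rep(1, 10), rep(0, 10)), yt, 1)$auc, 1)
  expect_equal(ovr_roc(rep(0.5, 20), yt, 1)$auc, 0.5)

  set.seed(53)
  for (n in c(20, 80, 200)) {
    y <- sample(1:6, n, replace = TRUE)
    while (length(unique(y)) < 2) y <- sample(1:6, n, replace = TRUE)
    s <- round(y / 6 + rnorm(n, 0, 0.4), 2)  # rounding forces ties
    for (k in unique(y)) {
      roc <- ovr_roc(s, y, k)
      expect_equal(roc$auc, brute_auc(s, y, k), tolerance = 1e-9)
      expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
      expect_true(all(roc$fpr >= 0 & roc$fpr <= 1))
    }
  }
  expect_error(ovr_roc(1:5, rep(1, 5), 1), "positive and negative")
})

test_that("ANFIS crisp outputs convert to distance-based class scores", {
  sc <- anfis_class_scores(c(1.1, 5.9, NA))
  expect_equal(dim(sc), c(3, 6))
  expect_equal(as.integer(which.max(sc[1, ])), 1L)
  expect_equal(as.integer(which.max(sc[2, ])), 6L)
  expect_true(all(sc[3, ] == min(sc)))  # out-of-range scores worst
})

test_that("stratified folds are balanced, seeded and reproducible", {
  fix <- separable_features(n_per_class = 10)
  cv <- kfold_cv(fix$X, fix$y, k = 5, model = "svm", seed = 3L)
  expect_equal(as.vector(table(cv$folds)), rep(12, 5))
  for (f in 1:5) {
    expect_equal(as.vector(table(fix$y[cv$folds == f])), rep(2, 6))
  }
  cv2 <- kfold_cv(fix$X, fix$y, k = 5, model = "svm", seed = 3L)
  expect_identical(cv$folds, cv2$folds)
  expect_equal(cv$mean_accuracy, cv2$mean_accuracy)
  expect_equal(cv$mean_accuracy, mean(cv$fold_accuracy))
  small <- separable_features(n_per_class = 3)
  expect_error(kfold_cv(small$X, small$y, k = 5, model = "svm"),
               "at least k members")
})

test_that("trace records flag outliers against the label bands", {
  tr <- trace_records(c(1, 2, 3), c(1, 2, 3), mode = "svm")
  expect_false(any(tr$outlier))
  tr2 <- trace_records(c(1, 2), c(1.75, 2.1), mode = "anfis")
  expect_equal(tr2$lower, c(0.5, 1.5))
  expect_equal(tr2$upper, c(1.4, 2.4))
  expect_true(tr2$outlier[1])    # 1.75 outside [0.5, 1.4]
  expect_false(tr2$outlier[2])   # 2.1 inside [1.5, 2.4]
  tr3 <- trace_records(4, NA_real_, mode = "anfis")
  expect_true(tr3$outlier)
})

test_that("the evaluation report assembles CM, metrics and per-class AUCs", {
  fix <- separable_features(n_per_class = 5)
  fit <- train_svm(fix$X, fix$y)
  pred <- predict_svm(fit, fix$X)
  rep <- eval_report(fix$y, pred$label, pred$posterior)
  expect_equal(rep$accuracy, 1)
  expect_equal(nrow(rep$per_class), 6)
  aucs <- vapply(rep$roc, function(r) r$auc, 0)
  expect_true(all(aucs == 1))
})
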
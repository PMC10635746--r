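test_that("stratified folds partition the data with balanced sizes", {
  labels <- c(rep("benign", 64), rep("malignant", 51))
  split <- kfold_split(115, 5, seed = 3, labels = labels)
  expect_identical(vapply(split$test, length, integer(1)), rep(23L, 5))
  all_test <- sort(unlist(split$test))
  expect_identical(all_test, 1:115)
  # per-class proportions within one sample
  for (f in 1:5) {
    nb <- sum(labels[split$test[[f]]] == "benign")
    expect_true(nb %in% c(12L, 13L))
  }
  expect_identical(kfold_split(115, 5, seed = 3, labels = labels)$test,
                   split$test)
  expect_false(identical(kfold_split(115, 5, seed = 4,
                                     labels = labels)$test, split$test))
  expect_error(kfold_split(4, 5), ">=")
})

test_that("confusion counts match a hand tally", {
  truth <- c("benign", "benign", "benign", "malignant", "malignant",
             "ignorant", "ignorant", "benign", "malignant", "benign")
  pred <- c("benign", "malignant", "benign", "malignant", "benign",
            "ignorant", "benign", "benign", "malignant", "ignorant")
  cm <- confusion_counts(truth, pred, positive = "benign")
  # benign truths: 5 -> predicted benign 3 (TP), malignant 1, ignorant 1 (FN)
  expect_identical(cm$TP, 3L)
  expect_identical(cm$FN, 2L)
  # malignant truths: 3 -> predicted benign 1 (FP), else TN
  expect_identical(cm$FP, 1L)
  expect_identical(cm$TN, 2L)
  expect_identical(cm$total, 8L)
  expect_identical(as.vector(cm$grid["benign", ]), c(3L, 1L, 1L))

  perfect <- confusion_counts(truth, truth, positive = "malignant")
  expect_identical(perfect$FN + perfect$FP, 0L)

  flip <- ifelse(truth == "benign", "malignant",
                 ifelse(truth == "malignant", "benign", "ignorant"))
  fcm <- confusion_counts(truth, flip, positive = "benign")
  expect_identical(fcm$TP + fcm$TN, 0L)
  expect_error(confusion_counts(truth, rep("odd", 10)), "unknown label")
})

test_that("metrics follow their defining ratios", {
  m <- classification_metrics(list(TP = 63, FN = 1, FP = 0, TN = 51))
  expect_equal(m[["sensitivity"]], 63 / 64)
  expect_equal(m[["specificity"]], 1.0)
  expect_equal(m[["accuracy"]], 114 / 115)

  all_right <- classification_metrics(list(TP = 10, FN = 0, FP = 0, TN = 5))
  expect_true(all(all_right == 1))
  expect_equal(classification_metrics(
    list(TP = 4, FN = 4, FP = 0, TN = 2))[["sensitivity"]], 0.5)
  und <- classification_metrics(list(TP = 0, FN = 0, FP = 1, TN = 3))
  expect_true(is.na(und[["sensitivity"]]))
  expect_false(is.na(und[["specificity"]]))
})

test_that("ROC curves behave under separation, noise and monotone maps", {
  truth <- rep(c("benign", "malignant"), each = 20)
  sep <- c(runif(20, 0.6, 1), runif(20, 0, 0.4))
  r <- roc_points(truth, sep, positive = "benign")
  expect_true(any(r$fpr == 0 & r$tpr == 1))
  expect_equal(unlist(r[1, ], use.names = FALSE), c(0, 0))
  expect_equal(unlist(r[nrow(r), ], use.names = FALSE), c(1, 1))
  expect_true(all(diff(r$fpr) >= 0))
  expect_true(all(diff(r$tpr) >= 0))
  expect_equal(attr(r, "auc"), 1)

  set.seed(21)
  truth2 <- sample(rep(c("benign", "malignant"), each = 1000))
  sc <- runif(2000)
  r2 <- roc_points(truth2, sc, positive = "benign")
  expect_lt(abs(attr(r2, "auc") - 0.5), 0.05)

  # strictly monotone transform leaves the curve unchanged
  r3 <- roc_points(truth2, qlogis(sc), positive = "benign")
  expect_equal(r2$fpr, r3$fpr)
  expect_equal(r2$tpr, r3$tpr)
  # reversing scores complements the AUC
  r4 <- roc_points(truth2, -sc, positive = "benign")
  expect_equal(attr(r4, "auc"), 1 - attr(r2, "auc"), tolerance = 1e-12)

  expect_error(roc_points(rep("benign", 5), runif(5)), "single class")
  expect_error(roc_points(truth2, c(NA, sc[-1])), "finite")
})

test_that("metrics are invariant to sample order", {
  set.seed(2)
  truth <- sample(mass_classes(), 60, TRUE)
  pred <- sample(mass_classes(), 60, TRUE)
  o <- sample(60)
  a <- classification_metrics(confusion_counts(truth, pred, "malignant"))
  b <- classification_metrics(confusion_counts(truth[o], pred[o],
                                               "malignant"))
  expect_identical(a, b)
})
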
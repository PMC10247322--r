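cm <- function(TP, TN, FP, FN) {
  structure(list(TP = TP, TN = TN, FP = FP, FN = FN),
            class = "confusion_matrix")
}

test_that("the six metrics evaluate their formulas exactly", {
  m <- compute_metrics(cm(50, 40, 10, 0))
  expect_equal(unname(m["accuracy"]), 0.90)
  expect_equal(unname(m["precision"]), 50 / 60)
  expect_equal(unname(m["npv"]), 1.0)
  expect_equal(unname(m["sensitivity"]), 1.0)
  expect_equal(unname(m["specificity"]), 0.80)
  expect_equal(unname(m["f1"]), 100 / 110)

  # perfect classifier
  expect_true(all(compute_metrics(cm(10, 10, 0, 0)) == 1))

  # all-positive predictor on a balanced set
  m2 <- compute_metrics(cm(10, 0, 10, 0))
  expect_equal(unname(m2["sensitivity"]), 1)
  expect_equal(unname(m2["specificity"]), 0)
  expect_equal(unname(m2["accuracy"]), 0.5)
})

test_that("undefined ratios are missing, never zero", {
  m <- compute_metrics(cm(0, 10, 0, 5))  # no positive predictions
  expect_true(is.na(m["precision"]))
  expect_identical(sort(attr(m, "undefined")), "precision")
  expect_error(compute_metrics(cm(0, 0, 0, 0)), "empty")
})

test_that("F1 is the precision-sensitivity harmonic mean whenever defined", {
  set.seed(20)
  for (i in 1:50) {
    x <- cm(sample(0:30, 1), sample(0:30, 1), sample(0:30, 1), sample(0:30, 1))
    if (x$TP + x$TN + x$FP + x$FN == 0) next
    m <- compute_metrics(x)
    p <- m[["precision"]]; s <- m[["sensitivity"]]
    if (!is.na(p) && !is.na(s) && p + s > 0) {
      expect_equal(m[["f1"]], 2 * p * s / (p + s))
    }
  }
})

test_that("confusion counts always sum to the evaluated rows", {
  set.seed(21)
  truth <- sample(c("depressed", "control"), 100, replace = TRUE)
  pred <- sample(c("depressed", "control"), 100, replace = TRUE)
  x <- confusion_matrix(truth, pred)
  expect_identical(x$TP + x$TN + x$FP + x$FN, 100L)
})

test_that("CV folds partition rows and stratify the class ratio", {
  fm <- fake_feature_matrix(57, 39, n_cols = 3, seed = 30)  # 19:13 ratio
  set.seed(1)
  fold <- depscreen:::stratified_folds(fm$labels, 5)
  expect_identical(sort(unique(fold)), 1:5)
  expect_identical(length(fold), 96L)  # every row in exactly one fold
  for (f in 1:5) {
    n_dep <- sum(fm$labels[fold == f] == "depressed")
    n_tot <- sum(fold == f)
    # class counts within one row of the global per-fold expectation;
    # totals within one row per class
    expect_lte(abs(n_dep - 57 / 5), 1)
    expect_lte(abs(n_tot - 96 / 5), 2)
  }
  expect_error(depscreen:::stratified_folds(rep(c("a", "b"), c(3, 96)), 5),
               "stratification error")
})

test_that("run_cv reports are deterministic and well-formed", {
  fm <- fake_feature_matrix(40, 30, n_cols = 4, seed = 31, informative = TRUE)
  r1 <- run_cv(fm, "fine_knn", folds = 5, iterations = 3, seed = 9)
  r2 <- run_cv(fm, "fine_knn", folds = 5, iterations = 3, seed = 9)
  expect_identical(r1, r2)
  expect_identical(nrow(r1$per_iteration), 3L)
  expect_true(all(r1$summary$sd >= 0))
  expect_true(all(r1$summary$mean >= 0 & r1$summary$mean <= 1))
  r3 <- run_cv(fm, "fine_knn", folds = 5, iterations = 3, seed = 10)
  expect_false(identical(r1$per_iteration, r3$per_iteration))
})

test_that("the 70/30 split reproduces the hold-out arithmetic", {
  fm <- fake_feature_matrix(1140, 780, n_cols = 2, seed = 32)
  set.seed(1)
  in_train <- depscreen:::stratified_split(fm$labels, 0.7)
  expect_identical(sum(in_train), 1344L)
  expect_identical(sum(!in_train), 576L)
  expect_identical(sum(in_train & fm$labels == "depressed"), 798L)

  r <- run_split_cv(fake_feature_matrix(40, 30, n_cols = 4, seed = 33,
                                        informative = TRUE),
                    "fine_knn", iterations = 3, seed = 2)
  per <- r$per_iteration
  expect_true(all(per >= 0 & per <= 1, na.rm = TRUE))
  expect_equal(per$overall_accuracy,
               0.7 * per$training_accuracy + 0.3 * per$testing_accuracy)
  r2 <- run_split_cv(fake_feature_matrix(40, 30, n_cols = 4, seed = 33,
                                         informative = TRUE),
                     "fine_knn", iterations = 3, seed = 2)
  expect_identical(r, r2)
})

test_that("subject-grouped CV keeps subjects whole and validates inputs", {
  fm <- fake_feature_matrix(50, 50, n_cols = 3, seed = 34)
  fm$subject_ids <- paste0("S", rep(1:10, each = 10))
  fm$labels <- rep(c("depressed", "control"), each = 50)
  r <- run_grouped_cv(fm, "fine_knn", folds = 5, iterations = 2, seed = 1)
  expect_identical(nrow(r$per_iteration), 2L)

  few <- fm_rows_for_test(fm, 1:40)  # 4 subjects only
  expect_error(run_grouped_cv(few, "fine_knn", folds = 5), "fewer subjects")
})

test_that("segment-level CV inflates accuracy on clustered cohorts", {
  segs <- preprocess_cohort(clustered_cohort(), "AB", 5)
  fm <- build_feature_matrix(segs, "hjorth_entropy")
  seg_cv <- run_cv(fm, "fine_knn", iterations = 5, seed = 3)
  sub_cv <- run_grouped_cv(fm, "fine_knn", folds = 4, iterations = 5, seed = 3)
  seg_acc <- seg_cv$summary$mean[seg_cv$summary$metric == "accuracy"]
  sub_acc <- sub_cv$summary$mean[sub_cv$summary$metric == "accuracy"]
  expect_gte(seg_acc, sub_acc)
})

test_that("without subject clustering the two CV granularities agree", {
  eff <- effect_spec(subject_sd = 0)
  coh <- generate_cohort(8, 8, duration_s = 60, seed = 29, effect = eff)
  fm <- build_feature_matrix(preprocess_cohort(coh, "AB", 5), "hjorth_entropy")
  seg_cv <- run_cv(fm, "fine_knn", iterations = 5, seed = 3)
  sub_cv <- run_grouped_cv(fm, "fine_knn", folds = 4, iterations = 5, seed = 3)
  seg_acc <- seg_cv$summary$mean[seg_cv$summary$metric == "accuracy"]
  sub_acc <- sub_cv$summary$mean[sub_cv$summary$metric == "accuracy"]
  expect_lt(abs(seg_acc - sub_acc), 0.02)
})
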
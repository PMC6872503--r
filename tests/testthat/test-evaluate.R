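test_that("metric identities hold for canonical predictors", {
  ## perfect predictor
  m <- evaluate_predictions(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(unlist(m[c("accuracy", "sensitivity", "specificity", "auc")]),
               c(accuracy = 1, sensitivity = 1, specificity = 1, auc = 1))
  ## always-control predictor on a 51 case / 100 control cohort
  labels <- c(rep(1L, 51), rep(0L, 100))
  m <- evaluate_predictions(rep(0, 151), labels)
  expect_equal(m$accuracy, 100 / 151)
  expect_equal(m$sensitivity, 0)
  expect_equal(m$specificity, 1)
})

test_that("metrics are reported missing when a class is absent", {
  m <- evaluate_predictions(c(0.2, 0.7), c(1, 1))
  expect_true(is.na(m$specificity))
  expect_true(is.na(m$auc))
  expect_false(is.na(m$sensitivity))
})

test_that("AUC of random scores is centred at one half", {
  labels <- rep(0:1, each = 40)
  aucs <- sapply(1:100, function(r)
    evaluate_predictions(withr::with_seed(r, runif(80)), labels)$auc)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("rank-statistic AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  for (r in 1:20) {
    labels <- withr::with_seed(r, rbinom(60, 1, 0.4))
    if (length(unique(labels)) < 2) next
    scores <- withr::with_seed(100 + r, rnorm(60) + labels)
    ours <- evaluate_predictions(scores, labels)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("cross-validation partitions subjects and blocks augmentation leaks", {
  co <- strong_cohort(grid = 8L, n_cases = 17L, n_controls = 33L, seed = 6L)
  cv <- crossvalidate(co$volumes, co$labels, k = 5, seed = 2,
                      arch = test_arch(),
                      augment = augmentation_config(balance = TRUE),
                      hyperparams = list(lr = 1e-3, epochs = 1L, batch_size = 16L),
                      subject_ids = co$subject_ids)
  ## every subject in exactly one test fold
  expect_identical(sort(unique(cv$folds)), 1:5)
  expect_length(cv$folds, 50)
  for (f in 1:5) {
    test_ids <- co$subject_ids[cv$folds == f]
    ## no augmented copy of a held-out subject in that fold's training data
    expect_length(intersect(cv$train_subjects[[f]], test_ids), 0)
  }
})

test_that("cross-validation metrics are invariant to subject ordering", {
  co <- strong_cohort(grid = 8L, n_cases = 6L, n_controls = 6L, seed = 8L)
  hp <- list(lr = 1e-3, epochs = 2L, batch_size = 4L)
  cv1 <- crossvalidate(co$volumes, co$labels, k = 3, seed = 5,
                       arch = test_arch(), hyperparams = hp,
                       subject_ids = co$subject_ids)
  perm <- withr::with_seed(1, sample(12))
  cv2 <- crossvalidate(co$volumes[perm], co$labels[perm], k = 3, seed = 5,
                       arch = test_arch(), hyperparams = hp,
                       subject_ids = co$subject_ids[perm])
  expect_equal(cv1$mean, cv2$mean)
  expect_equal(cv1$case_prob[perm], cv2$case_prob)
  expect_error(crossvalidate(co$volumes, co$labels, k = 7, arch = test_arch()),
               "at least k")
})

test_that("permuted labels drive cross-validated accuracy to chance", {
  co <- strong_cohort(grid = 12L, n_cases = 10L, n_controls = 10L, seed = 9L)
  labels <- withr::with_seed(13, sample(co$labels))
  cv <- crossvalidate(co$volumes, labels, k = 5, seed = 3,
                      arch = test_arch(),
                      hyperparams = list(lr = 1e-3, epochs = 5L, batch_size = 8L))
  expect_gte(cv$mean[["accuracy"]], 0.35)
  expect_lte(cv$mean[["accuracy"]], 0.65)
})
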